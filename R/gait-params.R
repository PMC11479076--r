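#' Joint angle range from a pair of tolerance ellipses
#'
#' The angle-range surrogate for joint excursion: the angle subtended at the
#' proximal keypoint's ellipse center by the two endpoints of the distal
#' keypoint's ellipse major axis. Joint pairing is proximal to next-distal:
#' shoulder-elbow, elbow-hand, hip-knee, knee-heel.
#'
#' @param proximal_ellipse,distal_ellipse `tolerance_ellipse` objects fitted
#'   on the same plane.
#' @return Angle in degrees in `[0, 180]`; 0 when the distal ellipse is fully
#'   degenerate (`semi_major = 0`).
#' @export
joint_angle_range <- function(proximal_ellipse, distal_ellipse) {
  if (distal_ellipse$semi_major <= 0) return(0)
  ep <- major_axis_endpoints(distal_ellipse)
  v1 <- ep[1, ] - proximal_ellipse$center
  v2 <- ep[2, ] - proximal_ellipse$center
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-12 || n2 < 1e-12) {
    stop("degenerate geometry: proximal center coincides with a distal ",
         "major-axis endpoint", call. = FALSE)
  }
  deg(acos(clamp1(sum(v1 * v2) / (n1 * n2))))
}

#' Lateral outward deviation between ellipse centers on the axial plane
#'
#' Signed lateral (axial x) deviation of a distal keypoint's ellipse center
#' from its proximal reference, per side and combined. Axial x > 0 is the
#' subject's right, so outward (away from the midline) is `distal - proximal`
#' on the right and its negation on the left. Positive = outward (abducted),
#' negative = inward.
#'
#' @param proximal_x,distal_x Named numeric vectors with elements `left` and
#'   `right`: axial-plane ellipse-center x coordinates (`NA` for a missing
#'   side).
#' @param bilateral `"mean"` (default) or `"sum"`: how the two sides combine.
#' @return List with `left`, `right`, `combined`, and `one_sided` (`TRUE`
#'   when only one side was available).
#' @export
lateral_outward_deviation <- function(proximal_x, distal_x,
                                      bilateral = c("mean", "sum")) {
  bilateral <- match.arg(bilateral)
  right <- unname(distal_x["right"] - proximal_x["right"])
  left <- unname(-(distal_x["left"] - proximal_x["left"]))
  sides <- c(left, right)
  ok <- !is.na(sides)
  combined <- if (!any(ok)) NA_real_
              else if (bilateral == "mean") mean(sides[ok])
              else sum(sides[ok])
  list(left = left, right = right, combined = combined,
       one_sided = sum(ok) == 1)
}

#' Leg outward shift on the axial plane
#'
#' Wide-based-gait metric, in fractions of leg length (the lower-limb
#' normalization): heel shift = lateral deviation of the heel ellipse center
#' from the hip's, toe shift = deviation of the toe from the heel, and
#' leg shift = heel shift + toe shift (exactly, by construction).
#'
#' @param hip_x,heel_x,toe_x Named (`left`, `right`) axial-plane
#'   ellipse-center x coordinates in leg-length units.
#' @param bilateral Per-side combination rule, see
#'   [lateral_outward_deviation()].
#' @return Tibble with columns `shift` (`heel`, `toe`, `leg`), `left`,
#'   `right`, `combined`.
#' @export
leg_outward_shift <- function(hip_x, heel_x, toe_x,
                              bilateral = c("mean", "sum")) {
  bilateral <- match.arg(bilateral)
  heel <- lateral_outward_deviation(hip_x, heel_x, bilateral)
  toe <- lateral_outward_deviation(heel_x, toe_x, bilateral)
  chain_shift_table(c("heel", "toe", "leg"), heel, toe)
}

#' Arm outward shift on the axial plane
#'
#' Upper-limb analogue of [leg_outward_shift()], in fractions of upper-body
#' length: elbow shift = deviation of the elbow ellipse center from the
#' shoulder's, hand shift = deviation of the hand from the elbow, and
#' arm shift = elbow shift + hand shift.
#'
#' @param shoulder_x,elbow_x,hand_x Named (`left`, `right`) axial-plane
#'   ellipse-center x coordinates in upper-body-length units.
#' @param bilateral Per-side combination rule.
#' @return Tibble with columns `shift` (`elbow`, `hand`, `arm`), `left`,
#'   `right`, `combined`.
#' @export
arm_outward_shift <- function(shoulder_x, elbow_x, hand_x,
                              bilateral = c("mean", "sum")) {
  bilateral <- match.arg(bilateral)
  elbow <- lateral_outward_deviation(shoulder_x, elbow_x, bilateral)
  hand <- lateral_outward_deviation(elbow_x, hand_x, bilateral)
  chain_shift_table(c("elbow", "hand", "arm"), elbow, hand)
}

#' @noRd
chain_shift_table <- function(names3, prox, dist) {
  tibble::tibble(
    shift = names3,
    left = c(prox$left, dist$left, prox$left + dist$left),
    right = c(prox$right, dist$right, prox$right + dist$right),
    combined = c(prox$combined, dist$combined,
                 prox$combined + dist$combined)
  )
}

# joint -> distal keypoint pairing for angle ranges
#' @noRd
angle_pairing <- function() {
  c(shoulder = "elbow", elbow = "hand", hip = "knee", knee = "heel")
}

#' @noRd
joint_segment <- function(joint) {
  if (joint %in% c("shoulder", "elbow", "hand")) "upper" else "lower"
}

#' Compute all gait parameters of one measurement
#'
#' Runs the full pipeline: confidence filtering, per-frame body axes,
#' tri-planar projection with length normalization for both body segments,
#' tolerance-ellipse fits for every limb keypoint on every plane, then
#' * joint angle ranges (shoulder, elbow, hip, knee) on the sagittal and
#'   coronal planes,
#' * ellipse areas for shoulder, elbow, hand, hip, knee, heel, toe on all
#'   three planes,
#' * outward shifts (elbow, hand, arm; heel, toe, leg) on the axial plane,
#' each per side and as the left-right mean (shifts: combined per the
#' `bilateral` rule). Parameters whose ellipses cannot be fitted (too few
#' unmasked points) are reported as `NA`, never silently zero.
#'
#' @param series A [keypoint_series()].
#' @param config A [gait_config()].
#' @return Tidy tibble with `measurement_id`, `metric` (`angle_range`,
#'   `ellipse_area`, `outward_shift`), `plane`, `target` (joint, keypoint or
#'   shift name), `side` (`left`, `right`, `mean`), `value`.
#' @export
compute_gait_parameters <- function(series, config = gait_config()) {
  stopifnot(inherits(series, "keypoint_series"))
  series <- apply_confidence_filter(series, config$confidence_threshold)

  planar <- list(
    lower = project_measurement(series, "lower", config),
    upper = project_measurement(series, "upper", config)
  )
  ells <- lapply(planar, ellipse_table, coverage = config$coverage,
                 min_points = config$min_points,
                 axis_convention = config$axis_convention)

  get_ell <- function(segment, kp, plane) {
    t <- ells[[segment]]
    row <- t[t$keypoint == kp & t$plane == plane, ]
    if (nrow(row) != 1 || !row$ok) NULL else row$ellipse[[1]]
  }

  rows <- list()
  add <- function(metric, plane, target, side, value) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      measurement_id = series$measurement_id, metric = metric,
      plane = plane, target = target, side = side, value = unname(value))
  }

  # -- joint angle ranges on sagittal and coronal planes
  pairing <- angle_pairing()
  for (plane in c("sagittal", "coronal")) {
    for (joint in names(pairing)) {
      seg <- joint_segment(joint)
      vals <- c(left = NA_real_, right = NA_real_)
      for (side in c("left", "right")) {
        s <- substr(side, 1, 1)
        prox <- get_ell(seg, paste0(s, "_", joint), plane)
        dist <- get_ell(seg, paste0(s, "_", pairing[[joint]]), plane)
        if (!is.null(prox) && !is.null(dist)) {
          vals[side] <- joint_angle_range(prox, dist)
        }
        add("angle_range", plane, joint, side, vals[side])
      }
      add("angle_range", plane, joint, "mean",
          if (anyNA(vals)) NA_real_ else mean(vals))
    }
  }

  # -- ellipse areas, all planes
  area_kps <- c("shoulder", "elbow", "hand", "hip", "knee", "heel", "toe")
  for (plane in c("sagittal", "coronal", "axial")) {
    for (kp in area_kps) {
      seg <- joint_segment(kp)
      vals <- c(left = NA_real_, right = NA_real_)
      for (side in c("left", "right")) {
        e <- get_ell(seg, paste0(substr(side, 1, 1), "_", kp), plane)
        if (!is.null(e)) vals[side] <- e$area
        add("ellipse_area", plane, kp, side, vals[side])
      }
      add("ellipse_area", plane, kp, "mean",
          if (anyNA(vals)) NA_real_ else mean(vals))
    }
  }

  # -- outward shifts on the axial plane
  center_x <- function(segment, kp) {
    c(left = (get_ell(segment, paste0("l_", kp), "axial") %||%
                list(center = c(NA_real_, NA_real_)))$center[1],
      right = (get_ell(segment, paste0("r_", kp), "axial") %||%
                 list(center = c(NA_real_, NA_real_)))$center[1])
  }
  leg <- leg_outward_shift(center_x("lower", "hip"),
                           center_x("lower", "heel"),
                           center_x("lower", "toe"), config$bilateral)
  arm <- arm_outward_shift(center_x("upper", "shoulder"),
                           center_x("upper", "elbow"),
                           center_x("upper", "hand"), config$bilateral)
  for (tbl in list(leg, arm)) {
    for (i in seq_len(nrow(tbl))) {
      add("outward_shift", "axial", tbl$shift[i], "left", tbl$left[i])
      add("outward_shift", "axial", tbl$shift[i], "right", tbl$right[i])
      add("outward_shift", "axial", tbl$shift[i], "mean", tbl$combined[i])
    }
  }

  out <- dplyr::bind_rows(rows)
  attr(out, "normalizers") <- c(
    lower = attr(planar$lower, "normalizer"),
    upper = attr(planar$upper, "normalizer")
  )
  out
}

#' Analyze many measurements
#'
#' @param series_list List of [keypoint_series()].
#' @param config A [gait_config()].
#' @return Row-bound tidy parameter tibble (one block per measurement), with
#'   a `group` column taken from each series.
#' @export
compute_cohort_parameters <- function(series_list, config = gait_config()) {
  dplyr::bind_rows(lapply(series_list, function(s) {
    p <- compute_gait_parameters(s, config)
    p$group <- s$group
    p$subject_id <- s$subject_id
    p
  }))
}
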