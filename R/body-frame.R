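#' Unit normal of the plane through three points
#'
#' Orientation follows the right-handed cross product of the edge vectors
#' `(p2 - p1) x (p3 - p1)`; for trunk planes the convention is
#' (right point - navel) x (left point - navel), with the final forward sign
#' fixed at measurement level (see [compute_body_axes()]).
#'
#' @param p1,p2,p3 Numeric length-3 vectors.
#' @return Unit length-3 vector orthogonal to both edges.
#' @export
plane_unit_normal <- function(p1, p2, p3) {
  a <- rbind(p2 - p1)
  b <- rbind(p3 - p1)
  cr <- row_cross(a, b)
  nn <- row_norm(cr)
  if (!is.finite(nn) || nn < 1e-12 * max(row_norm(a), row_norm(b), 1e-300)) {
    stop("degenerate geometry: points are collinear or coincident",
         call. = FALSE)
  }
  as.numeric(cr / nn)
}

#' Forward body-axis vector
#'
#' The forward direction is the normalized composite (equal-weight sum) of
#' the upper trunk-plane normal (navel, shoulders) and the lower trunk-plane
#' normal (navel, hips).
#'
#' @param UF,DF Unit normals of the shoulder and hip trunk planes.
#' @return Unit forward vector.
#' @export
forward_vector <- function(UF, DF) {
  s <- UF + DF
  n <- sqrt(sum(s^2))
  if (n < 1e-9) {
    stop("degenerate geometry: trunk-plane normals are anti-parallel",
         call. = FALSE)
  }
  s / n
}

#' Body axes for a single frame
#'
#' Constructs the orthonormal body triad from one frame of keypoints: forward
#' `f` (composite of the two trunk-plane normals), down-axis `c` (toward the
#' hip midpoint, lower segment) or up-axis `cc` (toward the shoulder
#' midpoint, upper segment) orthogonalized against `f`, and lateral
#' `n = f x c` (or `f x cc`). All pairwise dot products vanish to 1e-9.
#' Global sign conventions (forward = direction of locomotion, lateral =
#' subject's right) are resolved per measurement by [compute_body_axes()].
#'
#' @param frame_keypoints Named list or matrix (rownames = keypoint names) of
#'   length-3 coordinates; must include `navel_center`, both shoulders and
#'   both hips, unmasked.
#' @param segment `"lower"` or `"upper"`.
#' @return List with `origin`, `UF`, `DF`, `f`, `c_axis`, `n`, `segment`
#'   (`c_axis` holds `c` for the lower segment, `cc` for the upper).
#' @export
body_axes <- function(frame_keypoints, segment = c("lower", "upper")) {
  segment <- match.arg(segment)
  get <- function(name) {
    p <- if (is.matrix(frame_keypoints)) frame_keypoints[name, ]
         else frame_keypoints[[name]]
    if (is.null(p) || anyNA(p)) {
      stop("missing keypoint required for body axes: ", name, call. = FALSE)
    }
    as.numeric(p)
  }
  navel <- get("navel_center")
  # The navel sits below the shoulders but above the hips, so the two trunk
  # triangles face opposite ways; edge order differs per plane so that both
  # normals point to the same side of the trunk before compositing.
  UF <- plane_unit_normal(navel, get("l_shoulder"), get("r_shoulder"))
  DF <- plane_unit_normal(navel, get("r_hip"), get("l_hip"))
  f <- forward_vector(UF, DF)
  target <- if (segment == "lower") {
    (get("l_hip") + get("r_hip")) / 2 - navel
  } else {
    (get("l_shoulder") + get("r_shoulder")) / 2 - navel
  }
  cvec <- target - sum(target * f) * f
  cn <- sqrt(sum(cvec^2))
  if (cn < 1e-9) {
    stop("degenerate geometry: trunk midline parallel to forward axis",
         call. = FALSE)
  }
  cvec <- cvec / cn
  nvec <- as.numeric(row_cross(rbind(f), rbind(cvec)))
  list(origin = navel, UF = UF, DF = DF, f = f, c_axis = cvec, n = nvec,
       segment = segment)
}

# Vectorized per-frame axes for a whole measurement, with the two
# measurement-level sign anchors applied.
#' @noRd
compute_body_axes <- function(series, segment = c("lower", "upper"),
                              config = gait_config()) {
  segment <- match.arg(segment)
  nav <- kp_matrix(series, "navel_center")
  rs <- kp_matrix(series, "r_shoulder"); ls <- kp_matrix(series, "l_shoulder")
  rh <- kp_matrix(series, "r_hip"); lh <- kp_matrix(series, "l_hip")

  valid <- !(rowSums(is.na(nav)) + rowSums(is.na(rs)) + rowSums(is.na(ls)) +
             rowSums(is.na(rh)) + rowSums(is.na(lh)) > 0)
  if (!any(valid)) {
    stop("no frame has all trunk keypoints unmasked", call. = FALSE)
  }

  # edge order per plane keeps the two normals on the same side of the trunk
  UF <- row_unit(row_cross(ls - nav, rs - nav))
  DF <- row_unit(row_cross(rh - nav, lh - nav))
  f <- row_unit(UF + DF)

  # Forward sign: feet point forward (toe midpoint ahead of heel midpoint on
  # average), or short-window navel velocity if requested.
  s_f <- orientation_sign(series, f, valid, config)
  f <- f * s_f

  target <- if (segment == "lower") (lh + rh) / 2 - nav
            else (ls + rs) / 2 - nav
  cvec <- target - row_dot(target, f) * f
  cvec <- row_unit(cvec)
  nvec <- row_cross(f, cvec)

  # Lateral sign: subject's right has positive lateral coordinate.
  ref <- if (segment == "lower") rh - nav else rs - nav
  s_n <- sign_or_one(mean(row_dot(ref, nvec)[valid], na.rm = TRUE))
  nvec <- nvec * s_n

  list(origin = nav, f = f, c_axis = cvec, n = nvec,
       valid = valid, segment = segment, s_f = s_f, s_n = s_n)
}

#' @noRd
sign_or_one <- function(x) if (is.finite(x) && x < 0) -1 else 1

#' @noRd
orientation_sign <- function(series, f, valid, config) {
  if (config$orientation == "foot") {
    tm <- (kp_matrix(series, "l_toe") + kp_matrix(series, "r_toe")) / 2
    hm <- (kp_matrix(series, "l_heel") + kp_matrix(series, "r_heel")) / 2
    sign_or_one(mean(row_dot(f, tm - hm)[valid], na.rm = TRUE))
  } else {
    w <- max(1L, as.integer(config$orientation_window))
    nav <- kp_matrix(series, "navel_center")
    n <- nrow(nav)
    if (n <= w) return(1)
    v <- (nav[(w + 1):n, , drop = FALSE] - nav[1:(n - w), , drop = FALSE]) *
      (series$fps / w)
    sign_or_one(mean(row_dot(f[1:(n - w), , drop = FALSE], v), na.rm = TRUE))
  }
}

#' Project keypoints of one frame onto the body-axis planes
#'
#' For each keypoint `p` with displacement `d = p - origin`, the projections
#' are: sagittal `(d.f, d.c)`, coronal `(d.f, d.n)`, axial `(d.n, d.c)`
#' (with `cc` in place of `c` for the upper segment). Positive axial x is the
#' subject's right when the axes come from [compute_body_axes()].
#'
#' @param frame_keypoints Named list/matrix of length-3 coordinates.
#' @param axes Result of [body_axes()].
#' @param keypoints Names to project (default: all provided).
#' @return Tibble with `keypoint`, `plane`, `x`, `y`.
#' @export
project_frame <- function(frame_keypoints, axes, keypoints = NULL) {
  if (is.list(frame_keypoints) && !is.matrix(frame_keypoints)) {
    frame_keypoints <- do.call(rbind, frame_keypoints)
  }
  keypoints <- keypoints %||% rownames(frame_keypoints)
  p <- frame_keypoints[keypoints, , drop = FALSE]
  d <- sweep(p, 2, axes$origin)
  df <- as.numeric(d %*% axes$f)
  dc <- as.numeric(d %*% axes$c_axis)
  dn <- as.numeric(d %*% axes$n)
  tibble::tibble(
    keypoint = rep(keypoints, 3),
    plane = rep(c("sagittal", "coronal", "axial"), each = length(keypoints)),
    x = c(df, df, dn),
    y = c(dc, dn, dc)
  )
}

#' Segment length normalizers
#'
#' The lower-limb normalizer is the total leg length: per side the per-frame
#' 3D length `|hip-knee| + |knee-heel|` (optionally plus `|heel-toe|`),
#' median over frames, averaged over sides. The upper-body normalizer is the
#' median 3D distance from the navel center to the head center.
#'
#' @param series A [keypoint_series()].
#' @param segment `"lower"` or `"upper"`.
#' @param config A [gait_config()].
#' @return Positive scalar.
#' @export
segment_normalizer <- function(series, segment = c("lower", "upper"),
                               config = gait_config()) {
  segment <- match.arg(segment)
  if (segment == "upper") {
    d <- row_norm(kp_matrix(series, "head_center") -
                    kp_matrix(series, "navel_center"))
    len <- stats::median(d, na.rm = TRUE)
  } else {
    side_len <- function(side) {
      hip <- kp_matrix(series, paste0(side, "_hip"))
      knee <- kp_matrix(series, paste0(side, "_knee"))
      heel <- kp_matrix(series, paste0(side, "_heel"))
      l <- row_norm(knee - hip) + row_norm(heel - knee)
      if (config$leg_definition == "hip_knee_heel_toe") {
        l <- l + row_norm(kp_matrix(series, paste0(side, "_toe")) - heel)
      }
      stats::median(l, na.rm = TRUE)
    }
    len <- mean(c(side_len("l"), side_len("r")))
  }
  if (!is.finite(len) || len <= 1e-12) {
    stop("degenerate geometry: zero or undefined segment length normalizer",
         call. = FALSE)
  }
  len
}

#' Project a measurement onto the body-axis planes
#'
#' Runs the full per-frame pipeline for one body segment: body axes each
#' frame (frames with masked trunk keypoints are skipped), tri-planar
#' projection of the segment's keypoints, and length normalization (leg
#' length = 1 for the lower limb, upper-body length = 1 for the upper limb).
#' Because the frame is rebuilt every frame from the subject's own trunk,
#' the result is invariant to any rigid motion of the input coordinates —
#' this is what makes circular walking analyzable.
#'
#' @param series A [keypoint_series()] (confidence-filter it first).
#' @param segment `"lower"` or `"upper"`.
#' @param config A [gait_config()].
#' @param keypoints Keypoints to project; defaults to the segment's set.
#' @param normalize Divide by the segment normalizer (default `TRUE`).
#' @return Long tibble `keypoint, plane, frame, x, y` (`NA` rows where the
#'   keypoint or the frame's trunk anchors are masked), with attributes
#'   `normalizer` and `axes`.
#' @export
project_measurement <- function(series, segment = c("lower", "upper"),
                                config = gait_config(), keypoints = NULL,
                                normalize = TRUE) {
  segment <- match.arg(segment)
  keypoints <- keypoints %||% segment_keypoints(segment)
  axes <- compute_body_axes(series, segment, config)
  nrm <- if (normalize) segment_normalizer(series, segment, config) else 1

  n <- n_frames(series)
  out <- vector("list", length(keypoints))
  for (i in seq_along(keypoints)) {
    k <- keypoints[[i]]
    p <- kp_matrix(series, k)
    d <- p - axes$origin
    df <- row_dot(d, axes$f)
    dc <- row_dot(d, axes$c_axis)
    dn <- row_dot(d, axes$n)
    df[!axes$valid] <- NA_real_
    dc[!axes$valid] <- NA_real_
    dn[!axes$valid] <- NA_real_
    out[[i]] <- tibble::tibble(
      keypoint = k,
      plane = rep(c("sagittal", "coronal", "axial"), each = n),
      frame = rep(seq_len(n) - 1L, 3),
      x = c(df, df, dn) / nrm,
      y = c(dc, dn, dc) / nrm
    )
  }
  res <- dplyr::bind_rows(out)
  attr(res, "normalizer") <- nrm
  attr(res, "axes") <- axes
  attr(res, "segment") <- segment
  res
}
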