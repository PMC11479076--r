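#' Keypoint vocabulary
#'
#' The pose estimator exports 24 named keypoints per frame. The analysis
#' pipeline requires 19 of them (trunk anchors, head, and the limb joints);
#' the remaining 5 are carried through I/O untouched but never used by the
#' projection or parameter computations.
#'
#' @return Character vector of keypoint names.
#' @export
#' @examples
#' pipeline_keypoints()
keypoint_vocabulary <- function() {
  c(pipeline_keypoints(),
    "l_eye", "r_eye", "neck", "chest", "hip_center")
}

#' @rdname keypoint_vocabulary
#' @export
pipeline_keypoints <- function() {
  c("navel_center", "head_center", "nose", "l_ear", "r_ear",
    "l_shoulder", "r_shoulder", "l_elbow", "r_elbow", "l_hand", "r_hand",
    "l_hip", "r_hip", "l_knee", "r_knee", "l_heel", "r_heel",
    "l_toe", "r_toe")
}

# Keypoints belonging to each body segment for projection/normalization.
#' @noRd
segment_keypoints <- function(segment) {
  switch(segment,
    lower = c("l_hip", "r_hip", "l_knee", "r_knee",
              "l_heel", "r_heel", "l_toe", "r_toe"),
    upper = c("l_shoulder", "r_shoulder", "l_elbow", "r_elbow",
              "l_hand", "r_hand"),
    stop("unknown segment: ", segment, call. = FALSE)
  )
}

#' Construct a keypoint series
#'
#' A keypoint series holds one measurement: per-frame 3D body-center-relative
#' coordinates and a confidence score for each named keypoint. Coordinates are
#' dimensionless (the capture app normalizes to body scale). Low-confidence
#' entries are masked explicitly rather than dropped, so frame alignment
#' across keypoints is always preserved.
#'
#' @param coords Numeric array `[n_frames, n_keypoints, 3]`; the third
#'   dimension is x, y, z. Column (keypoint) dimnames are required.
#' @param confidence Numeric matrix `[n_frames, n_keypoints]` in `[0, 1]`.
#'   Defaults to all 1.
#' @param mask Logical matrix, `TRUE` where an entry is excluded. Defaults to
#'   all `FALSE`.
#' @param fps Frames per second (default 30, the app's capture rate).
#' @param measurement_id,subject_id Identifiers.
#' @param group Cohort label: `"HD"`, `"PD"`, `"CM"`, `"healthy"` or
#'   `"unknown"`.
#' @param variant Which app channel the coordinates represent: `"smoothed"`
#'   (low-pass filtered, the default analysis input) or `"raw"`.
#' @param extra Optional tibble of additional per-frame columns preserved
#'   from file input.
#'
#' @return An object of class `keypoint_series`.
#' @export
keypoint_series <- function(coords, confidence = NULL, mask = NULL,
                            fps = 30, measurement_id = "m1",
                            subject_id = "s1", group = "unknown",
                            variant = c("smoothed", "raw"),
                            extra = NULL) {
  variant <- match.arg(variant)
  stopifnot(is.array(coords), length(dim(coords)) == 3, dim(coords)[3] == 3)
  kp <- dimnames(coords)[[2]]
  if (is.null(kp)) stop("coords must carry keypoint dimnames", call. = FALSE)
  n <- dim(coords)[1]
  if (is.null(confidence)) {
    confidence <- matrix(1, n, length(kp), dimnames = list(NULL, kp))
  }
  if (is.null(mask)) {
    mask <- matrix(FALSE, n, length(kp), dimnames = list(NULL, kp))
  }
  stopifnot(
    identical(dim(confidence), c(n, length(kp))),
    identical(dim(mask), c(n, length(kp))),
    fps > 0
  )
  if (any(confidence < 0 | confidence > 1, na.rm = TRUE)) {
    stop("confidence scores must lie in [0, 1]", call. = FALSE)
  }
  group <- match.arg(group, c("HD", "PD", "CM", "healthy", "unknown"))
  missing_req <- setdiff(pipeline_keypoints(), kp)
  if (length(missing_req) > 0) {
    stop("keypoint vocabulary is missing required names: ",
         paste(missing_req, collapse = ", "), call. = FALSE)
  }
  structure(
    list(
      measurement_id = measurement_id,
      subject_id = subject_id,
      group = group,
      fps = fps,
      variant = variant,
      keypoints = kp,
      coords = coords,
      confidence = confidence,
      mask = mask,
      extra = extra
    ),
    class = "keypoint_series"
  )
}

#' @export
print.keypoint_series <- function(x, ...) {
  cat("<keypoint_series> ", x$measurement_id,
      " (subject ", x$subject_id, ", group ", x$group, ")\n", sep = "")
  cat("  frames:   ", n_frames(x), " @ ", x$fps, " fps (",
      format(round(duration(x), 2)), " s)\n", sep = "")
  cat("  keypoints:", length(x$keypoints), "\n")
  cat("  variant:  ", x$variant, "\n", sep = "")
  cat("  masked:   ", sum(x$mask), " / ", length(x$mask), " entries\n",
      sep = "")
  invisible(x)
}

#' Series dimensions and timing
#'
#' @param series A `keypoint_series`.
#' @return `n_frames()` the frame count; `duration()` the measurement length
#'   in seconds (`n_frames / fps`); `frame_times()` the per-frame timestamps.
#' @export
n_frames <- function(series) dim(series$coords)[1]

#' @rdname n_frames
#' @export
duration <- function(series) n_frames(series) / series$fps

#' @rdname n_frames
#' @export
frame_times <- function(series) (seq_len(n_frames(series)) - 1) / series$fps

# n x 3 coordinate matrix of one keypoint, NA where masked.
#' @noRd
kp_matrix <- function(series, name) {
  if (!name %in% series$keypoints) {
    stop("keypoint not present in series: ", name, call. = FALSE)
  }
  m <- series$coords[, name, , drop = FALSE]
  dim(m) <- c(dim(series$coords)[1], 3)
  m[series$mask[, name], ] <- NA_real_
  m
}

#' Mask low-confidence keypoint entries
#'
#' Entries whose confidence score falls below the threshold are considered
#' unreliable pose estimates and excluded from all downstream calculations.
#' Masking is per keypoint per frame: other keypoints in the same frame are
#' unaffected, and masked entries remain in the series (explicit missing
#' values) so usable-point counts stay exact.
#'
#' @param series A `keypoint_series`.
#' @param threshold Confidence threshold in `[0, 1]`; scores strictly below
#'   it are masked. Default 0.7.
#' @return The series with an updated mask. Raising the threshold never
#'   unmasks an entry, and the operation is idempotent at a fixed threshold.
#' @export
apply_confidence_filter <- function(series, threshold = 0.7) {
  stopifnot(inherits(series, "keypoint_series"),
            threshold >= 0, threshold <= 1)
  series$mask <- series$mask | (series$confidence < threshold)
  series
}

#' Fraction of masked entries
#'
#' @param series A `keypoint_series`.
#' @param keypoints Optional subset of keypoint names.
#' @return Proportion of (frame, keypoint) entries currently masked.
#' @export
masked_fraction <- function(series, keypoints = NULL) {
  m <- series$mask
  if (!is.null(keypoints)) m <- m[, keypoints, drop = FALSE]
  mean(m)
}

#' Compare two keypoint series for equality
#'
#' Coordinates of masked entries are ignored (they are not meaningful and are
#' written as empty fields on disk); everything else — unmasked coordinates,
#' confidences, mask pattern, metadata — must agree exactly.
#'
#' @param a,b `keypoint_series` objects.
#' @param tol Numeric tolerance (0 for bit equality).
#' @return `TRUE` or `FALSE`.
#' @export
series_equal <- function(a, b, tol = 0) {
  if (!identical(a$keypoints, b$keypoints)) return(FALSE)
  if (n_frames(a) != n_frames(b) || a$fps != b$fps) return(FALSE)
  if (!identical(a$mask, b$mask)) return(FALSE)
  keep <- !a$mask
  ca <- a$coords; cb <- b$coords
  for (d in 1:3) {
    xa <- ca[, , d][keep]; xb <- cb[, , d][keep]
    if (any(abs(xa - xb) > tol | is.na(xa) != is.na(xb))) return(FALSE)
  }
  all(abs(a$confidence - b$confidence) <= tol)
}
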