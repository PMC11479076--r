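#' Pipeline configuration
#'
#' Collects the tunable choices of the analysis pipeline with their defaults.
#' All entries can be overridden by name.
#'
#' @param confidence_threshold Confidence score below which keypoint entries
#'   are excluded (default 0.7).
#' @param coverage Nominal coverage of the tolerance ellipses (default 0.75).
#' @param min_points Minimum unmasked points required to fit an ellipse
#'   (default 10).
#' @param axis_convention Ellipse-area convention: `"semi"` (pi * a * b with
#'   semi-axes, the true geometric area; default) or `"full"` (full axis
#'   lengths, 4x the geometric area).
#' @param leg_definition Segments summed for the leg-length normalizer:
#'   `"hip_knee_heel"` (default) or `"hip_knee_heel_toe"` (adds the
#'   heel-to-toe segment).
#' @param bilateral How per-side outward shifts combine into one value:
#'   `"mean"` (default, keeps leg-length-fraction units) or `"sum"`.
#' @param orientation Forward-sign anchor for the body frame: `"foot"`
#'   (default; forward chosen so toes lie ahead of heels on average) or
#'   `"velocity"` (forward aligned with the navel's short-window horizontal
#'   velocity — only meaningful when coordinates retain global translation).
#' @param orientation_window Frame window for the `"velocity"` anchor
#'   (default 5).
#'
#' @return A named list of class `gait_config`.
#' @export
gait_config <- function(confidence_threshold = 0.7,
                        coverage = 0.75,
                        min_points = 10,
                        axis_convention = c("semi", "full"),
                        leg_definition = c("hip_knee_heel",
                                           "hip_knee_heel_toe"),
                        bilateral = c("mean", "sum"),
                        orientation = c("foot", "velocity"),
                        orientation_window = 5) {
  structure(
    list(
      confidence_threshold = confidence_threshold,
      coverage = coverage,
      min_points = min_points,
      axis_convention = match.arg(axis_convention),
      leg_definition = match.arg(leg_definition),
      bilateral = match.arg(bilateral),
      orientation = match.arg(orientation),
      orientation_window = orientation_window
    ),
    class = "gait_config"
  )
}
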