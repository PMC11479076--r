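# Internal vector-geometry helpers. All work on n x 3 matrices row-wise so
# whole measurements are processed without per-frame loops.

#' @noRd
row_cross <- function(a, b) {
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

#' @noRd
row_norm <- function(a) sqrt(rowSums(a^2))

#' @noRd
row_unit <- function(a, tol = 1e-12) {
  n <- row_norm(a)
  bad <- is.finite(n) & n < tol
  if (any(bad, na.rm = TRUE)) {
    stop("degenerate geometry: zero-length vector cannot be normalized",
         call. = FALSE)
  }
  a / n
}

#' @noRd
row_dot <- function(a, b) rowSums(a * b)

#' @noRd
clamp1 <- function(x) pmin(1, pmax(-1, x))

#' @noRd
deg <- function(rad) rad * 180 / pi

#' @noRd
rad <- function(deg) deg * pi / 180

#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x
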