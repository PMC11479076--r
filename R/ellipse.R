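#' Fit a tolerance ellipse to a 2D point cloud
#'
#' The ellipse is the population-coverage ellipse of a bivariate normal model
#' fitted by moments: center = sample mean, axes from the eigen-decomposition
#' of the sample covariance (n - 1 denominator), semi-axis lengths scaled by
#' `sqrt(qchisq(coverage, 2))` so a normal population has probability
#' `coverage` of falling inside. At the default 75% coverage this is the
#' tolerance ellipse conventionally drawn over projected keypoint clouds.
#'
#' Rank-deficient clouds are not an error: all-identical points give a
#' degenerate ellipse with both semi-axes 0, a collinear cloud gives
#' `semi_minor = 0`, so downstream angle ranges stay computable.
#'
#' @param points Two-column matrix (or data frame) of coordinates; rows with
#'   `NA` are dropped.
#' @param coverage Nominal coverage fraction in (0, 1); default 0.75.
#' @param min_points Minimum number of complete points (default 10).
#' @param axis_convention `"semi"` (area = pi * semi_major * semi_minor, the
#'   geometric area; default) or `"full"` (full axis lengths, 4x).
#' @return A `tolerance_ellipse`: list with `center`, `semi_major`,
#'   `semi_minor`, `tilt_deg` (major-axis orientation in (-90, 90], 0 for
#'   isotropic clouds), `coverage`, `n_points`, `area`, `degenerate`.
#' @export
fit_tolerance_ellipse <- function(points, coverage = 0.75, min_points = 10,
                                  axis_convention = c("semi", "full")) {
  axis_convention <- match.arg(axis_convention)
  stopifnot(coverage > 0, coverage < 1)
  pts <- as.matrix(points)
  stopifnot(ncol(pts) == 2)
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  n <- nrow(pts)
  if (n < min_points) {
    stop("insufficient data: ", n, " points, need at least ", min_points,
         call. = FALSE)
  }
  ctr <- colMeans(pts)
  S <- stats::cov(pts)
  ev <- eigen(S, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  k <- sqrt(stats::qchisq(coverage, df = 2))
  a <- k * sqrt(lam[1])
  b <- k * sqrt(lam[2])

  # Isotropic covariance: major axis undefined, report tilt 0.
  iso <- lam[1] <= 0 || (lam[1] - lam[2]) <= 1e-9 * lam[1]
  tilt <- if (iso) 0 else {
    v <- ev$vectors[, 1]
    t <- deg(atan2(v[2], v[1]))
    t <- t %% 180
    if (t > 90) t <- t - 180
    if (t == -90) t <- 90
    t
  }
  ell <- structure(
    list(center = as.numeric(ctr), semi_major = a, semi_minor = b,
         tilt_deg = tilt, coverage = coverage, n_points = n,
         axis_convention = axis_convention,
         degenerate = b <= 0),
    class = "tolerance_ellipse"
  )
  ell$area <- ellipse_area(ell)
  ell
}

#' @export
print.tolerance_ellipse <- function(x, ...) {
  cat(sprintf(
    "<tolerance_ellipse> %.0f%% coverage, n = %d\n  center (%.4g, %.4g), semi-axes (%.4g, %.4g), tilt %.2f deg, area %.4g\n",
    100 * x$coverage, x$n_points, x$center[1], x$center[2],
    x$semi_major, x$semi_minor, x$tilt_deg, x$area))
  invisible(x)
}

#' Ellipse area
#'
#' `pi * semi_major * semi_minor` under the default `"semi"` convention (the
#' geometric area; a circle of radius r gives pi r^2). The `"full"`
#' convention multiplies the full axis lengths instead, yielding 4x the
#' geometric area.
#'
#' @param ellipse A `tolerance_ellipse`.
#' @return Non-negative area in squared normalized units.
#' @export
ellipse_area <- function(ellipse) {
  a <- ellipse$semi_major * ellipse$semi_minor * pi
  if (identical(ellipse$axis_convention, "full")) a <- 4 * a
  a
}

#' Endpoints of the major axis
#'
#' @param ellipse A `tolerance_ellipse`.
#' @return 2 x 2 matrix, one endpoint per row:
#'   `center +/- semi_major * (cos tilt, sin tilt)`.
#' @export
major_axis_endpoints <- function(ellipse) {
  u <- c(cos(rad(ellipse$tilt_deg)), sin(rad(ellipse$tilt_deg)))
  rbind(ellipse$center - ellipse$semi_major * u,
        ellipse$center + ellipse$semi_major * u)
}

#' Point-in-ellipse membership test
#'
#' Boundary-inclusive: `TRUE` where the quadratic form of `p - center` in the
#' ellipse's principal basis is at most 1.
#'
#' @param ellipse A non-degenerate `tolerance_ellipse`.
#' @param p Length-2 point or an n x 2 matrix of points.
#' @return Logical vector.
#' @export
point_in_ellipse <- function(ellipse, p) {
  if (ellipse$degenerate) {
    stop("degenerate ellipse: membership test undefined", call. = FALSE)
  }
  p <- if (is.null(dim(p))) matrix(p, ncol = 2) else as.matrix(p)
  d <- sweep(p, 2, ellipse$center)
  th <- rad(ellipse$tilt_deg)
  q1 <- d[, 1] * cos(th) + d[, 2] * sin(th)
  q2 <- -d[, 1] * sin(th) + d[, 2] * cos(th)
  (q1 / ellipse$semi_major)^2 + (q2 / ellipse$semi_minor)^2 <= 1 + 1e-12
}

#' Tabulate fitted ellipses
#'
#' Fits one tolerance ellipse per (keypoint, plane) cell of a projected
#' measurement and returns them as a tidy table; cells with fewer complete
#' points than `min_points` are flagged rather than fitted.
#'
#' @param planar Output of [project_measurement()].
#' @param coverage,min_points,axis_convention Passed to
#'   [fit_tolerance_ellipse()].
#' @return Tibble with `keypoint`, `plane`, `center_x`, `center_y`,
#'   `semi_major`, `semi_minor`, `tilt_deg`, `area`, `n_points`, `ok`, and a
#'   list-column `ellipse`.
#' @export
ellipse_table <- function(planar, coverage = 0.75, min_points = 10,
                          axis_convention = "semi") {
  cells <- dplyr::distinct(planar, .data$keypoint, .data$plane)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- planar[planar$keypoint == cells$keypoint[i] &
                    planar$plane == cells$plane[i], c("x", "y")]
    e <- tryCatch(
      fit_tolerance_ellipse(sub, coverage, min_points, axis_convention),
      error = function(err) NULL
    )
    if (is.null(e)) {
      tibble::tibble(keypoint = cells$keypoint[i], plane = cells$plane[i],
                     center_x = NA_real_, center_y = NA_real_,
                     semi_major = NA_real_, semi_minor = NA_real_,
                     tilt_deg = NA_real_, area = NA_real_,
                     n_points = sum(stats::complete.cases(sub)), ok = FALSE,
                     ellipse = list(NULL))
    } else {
      tibble::tibble(keypoint = cells$keypoint[i], plane = cells$plane[i],
                     center_x = e$center[1], center_y = e$center[2],
                     semi_major = e$semi_major, semi_minor = e$semi_minor,
                     tilt_deg = e$tilt_deg, area = e$area,
                     n_points = e$n_points, ok = TRUE, ellipse = list(e))
    }
  })
  dplyr::bind_rows(rows)
}
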