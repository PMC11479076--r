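# Shared fixtures and independent oracles, built in code at test time.

# Noise-free walker config: deterministic kinematics, no dropout.
clean_config <- function(archetype = "healthy", seed = 1, ...) {
  walker_config(archetype = archetype, noise_sd = 0, dropout_prob = 0,
                seed = seed, ...)
}

# Upright pose fixture with hand-worked axes: up = +z, forward = +y,
# subject's right = +x (right = forward x up).
#   UF: (l_sh - navel) x (r_sh - navel) = (0, 0.18, 0) -> (0,1,0)
#   DF: (r_hip - navel) x (l_hip - navel) = (0, 0.02, 0) -> (0,1,0)
#   f = (0,1,0); hip midpoint - navel = (0,0,-0.1) -> c = (0,0,-1)
#   n = f x c = (-1,0,0); upper: cc = (0,0,1), n = f x cc = (1,0,0)
tpose_frame <- function() {
  rbind(
    navel_center = c(0, 0, 0),
    r_shoulder = c(0.2, 0, 0.45),
    l_shoulder = c(-0.2, 0, 0.45),
    r_hip = c(0.1, 0, -0.1),
    l_hip = c(-0.1, 0, -0.1)
  )
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# Rigidly transform every coordinate of a series: p -> R p + t.
transform_series <- function(series, R = diag(3), t = c(0, 0, 0)) {
  for (k in series$keypoints) {
    m <- series$coords[, k, ]
    dim(m) <- c(dim(series$coords)[1], 3)
    series$coords[, k, ] <- m %*% t(R) + matrix(t, nrow(m), 3, byrow = TRUE)
  }
  series
}

# Reflect the walker left <-> right: mirror coordinates through the x = 0
# world plane and swap l_/r_ keypoint labels.
mirror_series <- function(series) {
  series$coords[, , 1] <- -series$coords[, , 1]
  kp <- series$keypoints
  swapped <- kp
  swapped[grepl("^l_", kp)] <- sub("^l_", "r_", kp[grepl("^l_", kp)])
  swapped[grepl("^r_", kp)] <- sub("^r_", "l_", kp[grepl("^r_", kp)])
  dimnames(series$coords)[[2]] <- swapped
  colnames(series$confidence) <- swapped
  colnames(series$mask) <- swapped
  ord <- match(kp, swapped)
  series$coords <- series$coords[, ord, , drop = FALSE]
  series$confidence <- series$confidence[, ord, drop = FALSE]
  series$mask <- series$mask[, ord, drop = FALSE]
  series
}

# Independent angle-range oracle: ellipse fit by SVD of the centered cloud,
# endpoint angle measured as an atan2 difference. Shares no code with
# joint_angle_range()/fit_tolerance_ellipse().
oracle_angle_range <- function(prox_pts, dist_pts, coverage = 0.75) {
  prox_pts <- as.matrix(prox_pts)[stats::complete.cases(prox_pts), ]
  dist_pts <- as.matrix(dist_pts)[stats::complete.cases(dist_pts), ]
  vertex <- colMeans(prox_pts)
  ctr <- colMeans(dist_pts)
  X <- sweep(dist_pts, 2, ctr)
  sv <- svd(X / sqrt(nrow(dist_pts) - 1))
  a <- sqrt(stats::qchisq(coverage, 2)) * sv$d[1]
  dir <- sv$v[, 1]
  e1 <- ctr + a * dir - vertex
  e2 <- ctr - a * dir - vertex
  d <- abs(atan2(e1[2], e1[1]) - atan2(e2[2], e2[1]))
  if (d > pi) d <- 2 * pi - d
  unname(d * 180 / pi)
}

planar_points <- function(planar, kp, plane) {
  as.matrix(planar[planar$keypoint == kp & planar$plane == plane,
                   c("x", "y")])
}

param_value <- function(params, metric, target, side = "mean",
                        plane = NULL) {
  sel <- params$metric == metric & params$target == target &
    params$side == side
  if (!is.null(plane)) sel <- sel & params$plane == plane
  params$value[sel]
}
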