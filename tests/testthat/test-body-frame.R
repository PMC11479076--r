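test_that("plane_unit_normal follows the right-handed edge convention", {
  expect_equal(plane_unit_normal(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
               c(0, 0, 1))
  expect_error(plane_unit_normal(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)),
               "collinear")
  set.seed(42)
  for (i in 1:20) {
    p <- matrix(rnorm(9), 3)
    n <- tryCatch(plane_unit_normal(p[1, ], p[2, ], p[3, ]),
                  error = function(e) NULL)
    if (is.null(n)) next
    expect_lt(abs(sum(n * (p[2, ] - p[1, ]))), 1e-9)
    expect_lt(abs(sum(n * (p[3, ] - p[1, ]))), 1e-9)
    expect_equal(sum(n^2), 1)
  }
})

test_that("forward_vector composites the trunk-plane normals equally", {
  v <- c(0, 0, 1)
  expect_equal(forward_vector(v, v), v)
  expect_equal(forward_vector(c(1, 0, 0), c(0, 1, 0)),
               c(1, 1, 0) / sqrt(2))
  expect_error(forward_vector(c(1, 0, 0), c(-1, 0, 0) + 1e-12),
               "anti-parallel")
})

test_that("body axes on the upright fixture equal the hand-worked triad", {
  fr <- tpose_frame()
  ax <- body_axes(fr, "lower")
  expect_equal(ax$f, c(0, 1, 0), tolerance = 1e-9)
  expect_equal(ax$c_axis, c(0, 0, -1), tolerance = 1e-9)
  expect_equal(ax$n, c(-1, 0, 0), tolerance = 1e-9)
  up <- body_axes(fr, "upper")
  expect_equal(up$c_axis, c(0, 0, 1), tolerance = 1e-9)
  expect_equal(up$n, c(1, 0, 0), tolerance = 1e-9)

  fr2 <- fr
  fr2["l_hip", ] <- NA
  expect_error(body_axes(fr2, "lower"), "missing keypoint")
})

test_that("every emitted body frame is orthonormal to 1e-9", {
  s <- generate_walk(walker_config(seed = 8, noise_sd = 0.01,
                                   dropout_prob = 0))
  for (segment in c("lower", "upper")) {
    ax <- gaitplanes:::compute_body_axes(s, segment)
    v <- ax$valid
    expect_lt(max(abs(rowSums(ax$f[v, ] * ax$c_axis[v, ]))), 1e-9)
    expect_lt(max(abs(rowSums(ax$f[v, ] * ax$n[v, ]))), 1e-9)
    expect_lt(max(abs(rowSums(ax$n[v, ] * ax$c_axis[v, ]))), 1e-9)
    for (m in list(ax$f, ax$c_axis, ax$n)) {
      expect_lt(max(abs(rowSums(m[v, ]^2) - 1)), 1e-9)
    }
  }
})

test_that("axes are exactly equivariant under rigid rotation", {
  fr <- tpose_frame()
  set.seed(7)
  for (i in 1:5) {
    R <- random_rotation()
    frR <- fr %*% t(R)
    rownames(frR) <- rownames(fr)
    ax <- body_axes(fr, "lower")
    axR <- body_axes(frR, "lower")
    expect_equal(axR$f, as.numeric(R %*% ax$f), tolerance = 1e-9)
    expect_equal(axR$c_axis, as.numeric(R %*% ax$c_axis), tolerance = 1e-9)
    expect_equal(axR$n, as.numeric(R %*% ax$n), tolerance = 1e-9)
  }
})

test_that("projection basis cases and reconstruction oracle hold", {
  ax <- body_axes(tpose_frame(), "lower")
  pr <- function(p) {
    m <- rbind(navel_center = ax$origin, probe = p)
    project_frame(m, ax, keypoints = "probe")
  }
  at <- function(tab, plane) unlist(tab[tab$plane == plane, c("x", "y")],
                                    use.names = FALSE)
  zero <- pr(ax$origin)
  expect_true(all(abs(zero$x) < 1e-12 & abs(zero$y) < 1e-12))
  pf <- pr(ax$origin + ax$f)
  expect_equal(at(pf, "sagittal"), c(1, 0))
  expect_equal(at(pf, "coronal"), c(1, 0))
  expect_equal(at(pf, "axial"), c(0, 0))

  set.seed(11)
  for (i in 1:20) {
    p <- rnorm(3)
    tab <- pr(p)
    sag <- at(tab, "sagittal"); axl <- at(tab, "axial")
    # coordinates along f, c, n reconstruct the 3D point exactly
    rec <- ax$origin + sag[1] * ax$f + sag[2] * ax$c_axis + axl[1] * ax$n
    expect_equal(rec, p, tolerance = 1e-9)
  }
})

test_that("length normalizers recover the generator's configured lengths", {
  s <- generate_walk(clean_config(seed = 2))
  truth <- attr(s, "truth")
  expect_equal(segment_normalizer(s, "lower"), truth$leg_length,
               tolerance = 1e-9)
  expect_equal(segment_normalizer(s, "upper"), truth$upper_body_length,
               tolerance = 1e-9)

  # doubling the leg doubles the normalizer
  s2 <- generate_walk(clean_config(seed = 2, leg_length = 2 * 0.85,
                                   upper_body_length = 2 * 0.52))
  expect_equal(segment_normalizer(s2, "lower") / segment_normalizer(s2, "upper"),
               segment_normalizer(s, "lower") / segment_normalizer(s, "upper"),
               tolerance = 1e-9)
})

test_that("normalized projections are invariant to global scaling", {
  s <- generate_walk(clean_config(seed = 6))
  s_scaled <- s
  s_scaled$coords <- s$coords * 3.7
  a <- project_measurement(s, "lower")
  b <- project_measurement(s_scaled, "lower")
  expect_equal(a$x, b$x, tolerance = 1e-9)
  expect_equal(a$y, b$y, tolerance = 1e-9)
})

test_that("normalized projections are invariant to rigid motion", {
  s <- generate_walk(walker_config(seed = 13, noise_sd = 0.01,
                                   dropout_prob = 0))
  set.seed(99)
  s2 <- transform_series(s, random_rotation(), c(0.3, -1.2, 2.5))
  for (segment in c("lower", "upper")) {
    a <- project_measurement(s, segment)
    b <- project_measurement(s2, segment)
    expect_lt(max(abs(a$x - b$x), na.rm = TRUE), 1e-6)
    expect_lt(max(abs(a$y - b$y), na.rm = TRUE), 1e-6)
  }
})
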