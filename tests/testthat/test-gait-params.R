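mk_ell <- function(center, a = 1, b = 0.5, tilt = 0) {
  structure(list(center = center, semi_major = a, semi_minor = b,
                 tilt_deg = tilt, degenerate = b <= 0,
                 axis_convention = "semi"),
            class = "tolerance_ellipse")
}

test_that("joint angle range reproduces exact trigonometry", {
  prox <- mk_ell(c(0, 0), a = 0, b = 0)
  dist <- mk_ell(c(0, -1), a = 0.5, b = 0.1, tilt = 0)
  # endpoints (-0.5,-1), (0.5,-1) seen from the origin
  expect_equal(joint_angle_range(prox, dist), 2 * atan(0.5) * 180 / pi,
               tolerance = 1e-12)
  expect_equal(joint_angle_range(prox, mk_ell(c(0, -1), a = 0, b = 0)), 0)
  expect_error(joint_angle_range(mk_ell(c(0.5, -1)), dist), "degenerate")
})

test_that("outward deviation sign convention: positive = outward", {
  expect_equal(
    lateral_outward_deviation(c(left = -0.02, right = 0.02),
                              c(left = -0.05, right = 0.05))$combined,
    0.03)
  # inward drift gives a negative shift
  expect_equal(
    lateral_outward_deviation(c(left = -0.03, right = 0.03),
                              c(left = -0.01, right = 0.01))$combined,
    -0.02)
  z <- lateral_outward_deviation(c(left = -1, right = 1),
                                 c(left = -1, right = 1))
  expect_equal(z$combined, 0)
  one <- lateral_outward_deviation(c(left = NA, right = 0.02),
                                   c(left = NA, right = 0.05))
  expect_true(one$one_sided)
  expect_equal(one$combined, 0.03)
})

test_that("leg and arm chains are additive by construction", {
  leg <- leg_outward_shift(c(left = -0.1, right = 0.1),
                           c(left = -0.18, right = 0.18),
                           c(left = -0.22, right = 0.22))
  expect_equal(leg$combined[leg$shift == "leg"],
               leg$combined[leg$shift == "heel"] +
                 leg$combined[leg$shift == "toe"])
  expect_equal(leg$combined, c(0.08, 0.04, 0.12))

  arm <- arm_outward_shift(c(left = -0.2, right = 0.2),
                           c(left = -0.30, right = 0.30),
                           c(left = -0.25, right = 0.25))
  expect_equal(arm$combined, c(0.10, -0.05, 0.05))

  # collinear chain: all shifts zero
  same <- c(left = -0.1, right = 0.1)
  expect_equal(leg_outward_shift(same, same, same)$combined, c(0, 0, 0))
})

test_that("noise-free wide-base walker recovers its configured offsets", {
  cfg <- clean_config(archetype = gait_archetype(
    "custom", heel_lateral_offset = 0.08,
    toe_lateral_offset_beyond_heel = 0.04))
  p <- compute_gait_parameters(generate_walk(cfg))
  expect_equal(param_value(p, "outward_shift", "heel"), 0.08,
               tolerance = 1e-9)
  expect_equal(param_value(p, "outward_shift", "toe"), 0.04,
               tolerance = 1e-9)
  expect_equal(param_value(p, "outward_shift", "leg"), 0.12,
               tolerance = 1e-9)
})

test_that("offset recovery is linear with slope 1 across a sweep", {
  offsets <- c(0, 0.02, 0.04, 0.06, 0.08)
  est <- vapply(offsets, function(o) {
    cfg <- clean_config(archetype = gait_archetype(
      "custom", heel_lateral_offset = o))
    param_value(compute_gait_parameters(generate_walk(cfg)),
                "outward_shift", "heel")
  }, numeric(1))
  expect_equal(unname(coef(lm(est ~ offsets))[2]), 1, tolerance = 1e-6)
})

test_that("angle ranges equal the independent brute-force oracle", {
  cfg <- clean_config(seed = 21)
  s <- generate_walk(cfg)
  p <- compute_gait_parameters(s)
  planar <- list(lower = project_measurement(s, "lower"),
                 upper = project_measurement(s, "upper"))
  pairing <- c(shoulder = "elbow", elbow = "hand", hip = "knee",
               knee = "heel")
  for (plane in c("sagittal", "coronal")) {
    for (joint in names(pairing)) {
      seg <- if (joint %in% c("hip", "knee")) "lower" else "upper"
      for (side in c("l", "r")) {
        got <- param_value(p, "angle_range", joint,
                           side = c(l = "left", r = "right")[side],
                           plane = plane)
        want <- oracle_angle_range(
          planar_points(planar[[seg]], paste0(side, "_", joint), plane),
          planar_points(planar[[seg]], paste0(side, "_", pairing[joint]),
                        plane))
        expect_equal(got, want, tolerance = 1e-6)
      }
    }
  }
})

test_that("hip angle range grows strictly with hip swing amplitude", {
  amps <- c(5, 10, 15, 20, 25)
  vals <- vapply(amps, function(a) {
    cfg <- clean_config(archetype = gait_archetype(
      "custom", hip_swing_half_amp_deg = a))
    param_value(compute_gait_parameters(generate_walk(cfg)),
                "angle_range", "hip", plane = "sagittal")
  }, numeric(1))
  expect_true(all(diff(vals) > 0))

  sh <- vapply(c(4, 10, 16), function(a) {
    cfg <- clean_config(archetype = gait_archetype(
      "custom", shoulder_swing_half_amp_deg = a))
    param_value(compute_gait_parameters(generate_walk(cfg)),
                "angle_range", "shoulder", plane = "sagittal")
  }, numeric(1))
  expect_true(all(diff(sh) > 0))
})

test_that("mirroring the walker swaps sides and preserves combined values", {
  s <- generate_walk(clean_config(seed = 17))
  m <- mirror_series(s)
  a <- compute_gait_parameters(s)
  b <- compute_gait_parameters(m)
  merged <- merge(a, b, by = c("metric", "plane", "target", "side"),
                  suffixes = c("_orig", "_mirr"))
  for (i in seq_len(nrow(merged))) {
    row <- merged[i, ]
    if (row$side == "mean") {
      expect_equal(row$value_mirr, row$value_orig, tolerance = 1e-6)
    }
  }
  # per-side values swap
  swap <- merge(
    a[a$side == "left", c("metric", "plane", "target", "value")],
    b[b$side == "right", c("metric", "plane", "target", "value")],
    by = c("metric", "plane", "target"))
  expect_equal(swap$value.x, swap$value.y, tolerance = 1e-6)
})

test_that("identical input yields bit-identical parameters", {
  cfg <- walker_config(seed = 31, noise_sd = 0.01, dropout_prob = 0.1)
  p1 <- compute_gait_parameters(generate_walk(cfg))
  p2 <- compute_gait_parameters(generate_walk(cfg))
  expect_identical(p1$value, p2$value)
})

test_that("healthy beats HD on hip range; PD trails HD on arm swing", {
  ph <- compute_gait_parameters(generate_walk(clean_config("healthy", 5)))
  phd <- compute_gait_parameters(generate_walk(clean_config("HD", 5)))
  ppd <- compute_gait_parameters(generate_walk(clean_config("PD", 5)))
  expect_gt(param_value(ph, "angle_range", "hip", plane = "sagittal"),
            param_value(phd, "angle_range", "hip", plane = "sagittal"))
  expect_lt(param_value(ppd, "angle_range", "shoulder", plane = "sagittal"),
            param_value(phd, "angle_range", "shoulder", plane = "sagittal"))
  expect_lt(param_value(ppd, "angle_range", "elbow", plane = "sagittal"),
            param_value(phd, "angle_range", "elbow", plane = "sagittal"))
})
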