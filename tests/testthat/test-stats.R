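test_that("pearson_ci matches the hand-computed fixture to 1e-12", {
  # 10-pair fixture; expected values frozen from an explicit step-by-step
  # product-moment + Fisher-z computation (sum formulas, atanh/tanh).
  x <- c(2.1, 3.4, 1.8, 5.0, 4.2, 2.9, 3.7, 4.8, 1.2, 3.3)
  y <- c(1.0, 2.3, 1.1, 3.9, 3.0, 2.2, 2.4, 4.1, 0.4, 2.0)
  res <- pearson_ci(x, y)
  expect_equal(res$r, 0.980598948719985, tolerance = 1e-12)
  expect_equal(res$ci_low, 0.917361831662562, tolerance = 1e-12)
  expect_equal(res$ci_high, 0.995557319917191, tolerance = 1e-12)
  expect_identical(res$n, 10L)
})

test_that("perfect linear relation gives r = 1 with a degenerate CI", {
  x <- c(1, 2, 4, 7, 9)
  res <- pearson_ci(x, 2 * x + 1)
  expect_equal(res$r, 1)
  expect_equal(res$ci_low, 1)
  expect_equal(res$ci_high, 1)
})

test_that("independent samples give r near 0 with CI covering 0", {
  set.seed(2024)
  x <- rnorm(1e4); y <- rnorm(1e4)
  res <- pearson_ci(x, y)
  expect_lt(abs(res$r), 0.05)
  expect_lt(res$ci_low, 0)
  expect_gt(res$ci_high, 0)
})

test_that("pearson_ci guards its preconditions and deletes pairwise", {
  expect_error(pearson_ci(c(1, 2), c(1, 2)), "insufficient")
  expect_error(pearson_ci(rep(1, 5), 1:5), "zero variance")
  # NA pairs are dropped, unrelated values untouched
  x <- c(1, 2, 3, NA, 5, 6)
  y <- c(2, 4, 6, 8, NA, 12)
  res <- pearson_ci(x, y)
  expect_identical(res$n, 4L)
  expect_equal(res$r, 1)
})

test_that("r is symmetric, affine-invariant and sign-flips under negation", {
  set.seed(5)
  x <- rnorm(50); y <- x + rnorm(50)
  r0 <- pearson_ci(x, y)$r
  expect_equal(pearson_ci(y, x)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_ci(3 * x + 2, 0.5 * y - 1)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_ci(-x, y)$r, -r0, tolerance = 1e-12)
  # CI width shrinks with n at fixed r
  w <- vapply(c(10, 50, 200), function(n) {
    res <- pearson_ci(seq_len(n), seq_len(n) + rep(c(-1, 1), length.out = n))
    res$ci_high - res$ci_low
  }, numeric(1))
  expect_true(all(diff(w) < 0))
})

test_that("coupled hip and elbow amplitudes dominate the correlation table", {
  cc <- generate_cohort(c(HD = 0, PD = 0, CM = 0, healthy = 30),
                        seed = 77, noise_sd = 0.005, dropout_prob = 0,
                        coupling_sdlog = 0.35, subject_sdlog = 0.05)
  params <- compute_cohort_parameters(cc$series)
  tab <- parameter_correlation_table(params, by_group = FALSE)
  angles <- tab[grepl("angle", tab$upper), ]
  best <- angles[which.max(angles$r), ]
  expect_identical(best$upper, "elbow_angle")
  expect_identical(best$lower, "hip_angle")
  expect_gt(best$r, 0.5)
})

test_that("correlation table flags degenerate cells and ignores row order", {
  cc <- generate_cohort(c(HD = 0, PD = 0, CM = 0, healthy = 6),
                        seed = 3, noise_sd = 0, dropout_prob = 0,
                        coupling_sdlog = 0, subject_sdlog = 0,
                        measurement_sdlog = 0)
  params <- compute_cohort_parameters(cc$series)
  # clones: zero variance everywhere -> every cell flagged, none computed
  tab <- parameter_correlation_table(params, by_group = FALSE)
  expect_true(all(!tab$ok))
  expect_true(all(grepl("zero variance|insufficient", tab$note)))

  cc2 <- generate_cohort(c(HD = 3, PD = 0, CM = 0, healthy = 3),
                         seed = 8, noise_sd = 0.005, dropout_prob = 0)
  params2 <- compute_cohort_parameters(cc2$series)
  t1 <- parameter_correlation_table(params2, by_group = FALSE)
  shuffled <- params2[rev(seq_len(nrow(params2))), ]
  t2 <- parameter_correlation_table(shuffled, by_group = FALSE)
  expect_equal(t1$r, t2$r, tolerance = 1e-12)

  expect_error(parameter_correlation_table(params2, pairs = tibble::tibble(
    upper = character(), lower = character())), "empty pair")
})

test_that("group summaries report the distribution facts", {
  cc <- generate_cohort(c(HD = 1, PD = 1, CM = 1, healthy = 1),
                        seed = 12, noise_sd = 0, dropout_prob = 0)
  params <- compute_cohort_parameters(cc$series)
  sm <- group_distribution_summary(params)
  one <- sm[sm$group == "HD" & sm$metric == "angle_range" &
              sm$target == "hip" & sm$plane == "sagittal", ]
  expect_identical(one$n, 1L)
  expect_equal(one$mean,
               param_value(params[params$group == "HD", ],
                           "angle_range", "hip", plane = "sagittal"))
  expect_true(is.na(one$sd))  # single observation: SD is flagged missing

  shifted <- params
  sel <- shifted$metric == "angle_range" & shifted$target == "hip"
  shifted$value[sel] <- shifted$value[sel] + 10
  sm2 <- group_distribution_summary(shifted)
  m1 <- sm[sm$metric == "angle_range" & sm$target == "hip", ]
  m2 <- sm2[sm2$metric == "angle_range" & sm2$target == "hip", ]
  expect_equal(m2$mean, m1$mean + 10)

  bad <- params
  bad$group[1] <- "mystery"
  expect_error(group_distribution_summary(bad), "unknown group")
})
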