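test_that("descriptive statistics match hand-computed type-7 quantiles", {
  d <- descriptive_stats(c(5, 5, 5))
  expect_equal(d$mean, 5)
  expect_equal(d$median, 5)
  expect_equal(d$interquartile_range, 0)
  expect_equal(d$shift_range, c(5, 5))
  d2 <- descriptive_stats(c(1, 2, 3, 4))
  expect_equal(d2$mean, 2.5)
  expect_equal(d2$median, 2.5)
  # independent hand computation of the type-7 quartiles for n = 6:
  # h = (n - 1) p + 1; Q1 at h = 2.25, Q3 at h = 4.75
  v <- c(-3.6, -3.1, -2.9, -2.7, -2.3, -1.2)
  q1 <- v[2] + 0.25 * (v[3] - v[2])
  q3 <- v[4] + 0.75 * (v[5] - v[4])
  d3 <- descriptive_stats(v)
  expect_equal(d3$interquartile_range, q3 - q1, tolerance = 1e-12)
  expect_equal(d3$median, mean(v[3:4]))
  expect_equal(d3$shift_range, c(-3.6, -1.2))
  expect_error(descriptive_stats(1), ">= 2")
})

test_that("Bland-Altman limits are exact affine functions of mean and SD", {
  z <- bland_altman(rep(0, 5))
  expect_equal(z$mean_of_deviations, 0)
  expect_equal(z$standard_deviation, 0)
  expect_equal(c(z$limit_lower, z$limit_upper), c(0, 0))
  b <- bland_altman(c(-1, 0, 1), k = 2)
  expect_equal(b$mean_of_deviations, 0)
  expect_equal(b$standard_deviation, 1)
  expect_equal(b$limit_upper, 2)
  expect_equal(b$limit_lower, -2)
  # limits recompute bit-for-bit from the returned fields
  set.seed(21)
  x <- rnorm(40, -0.3, 0.8)
  ba <- bland_altman(x, k = 1.96)
  expect_identical(ba$limit_upper,
                   ba$mean_of_deviations + ba$k * ba$standard_deviation)
  expect_identical(ba$limit_lower,
                   ba$mean_of_deviations - ba$k * ba$standard_deviation)
})

test_that("one-sample t-test matches the closed-form statistic", {
  r <- one_sample_ttest(c(-1, 1))
  expect_equal(r$t_statistic, 0)
  expect_equal(r$p_value, 1)
  r2 <- one_sample_ttest(1:5)
  # hand formula: t = mean / (sd / sqrt(n))
  expect_equal(r2$t_statistic, 3 / (sqrt(2.5) / sqrt(5)), tolerance = 1e-12)
  expect_equal(r2$degrees_of_freedom, 4)
  expect_equal(r2$p_value, 2 * stats::pt(-r2$t_statistic, 4),
               tolerance = 1e-12)
  expect_lt(abs(r2$p_value - 0.0132), 5e-4)
  expect_error(one_sample_ttest(c(2, 2, 2)), "degenerate")
})

test_that("quadrature total error satisfies its bounds and rounding convention", {
  expect_equal(round_half_away(total_error(-0.48, -2.70)), 2.74)
  expect_equal(round_half_away(total_error(-0.19, 1.15)), 1.17)
  expect_equal(total_error(0, -3.2), 3.2)
  expect_equal(round_half_away(2.745), 2.75)
  expect_equal(round_half_away(-2.745), -2.75)
  set.seed(13)
  for (i in 1:100) {
    a <- runif(1, -5, 5); b <- runif(1, -5, 5)
    te <- total_error(a, b)
    expect_gte(te, max(abs(a), abs(b)))
    expect_lte(te, abs(a) + abs(b))
  }
})

test_that("error reports combine mean shifts with grouped registration errors", {
  tab <- simulate_cohort_shifts(cohort_config(n_per_setup = 4,
                                              offsets = rep(0, 6),
                                              spreads = rep(0, 6), seed = 1))
  rep0 <- build_error_report(tab, list(xy_mm = 0, z_mm = 0, rot_deg = 0))
  expect_true(all(rep0$te == 0))
  # grouped mRE assignment: x and y share xy, z its own, rotations pooled
  mre <- list(xy_mm = -0.48, z_mm = -0.19, rot_deg = 0.04)
  rep1 <- build_error_report(tab, mre)
  expect_equal(rep1$mre[rep1$component == "tx_mm"], rep(-0.48, 2))
  expect_equal(rep1$mre[rep1$component == "ty_mm"], rep(-0.48, 2))
  expect_equal(rep1$mre[rep1$component == "tz_mm"], rep(-0.19, 2))
  expect_equal(rep1$mre[rep1$component == "yaw_deg"], rep(0.04, 2))
  expect_error(build_error_report(tab, list(xy_mm = 1)), "rot_deg")
})

test_that("cohort pipeline recovers injected offsets through the error report", {
  off <- c(1.5, -2, 0.8, 0.5, -0.4, 0.2)
  spr <- c(1, 1, 2, 0.4, 0.4, 0.4)
  n <- 5000
  cfg <- cohort_config(n_per_setup = n, offsets = off, spreads = spr,
                       seed = 17)
  repc <- build_error_report(simulate_cohort_shifts(cfg),
                             list(xy_mm = 0, z_mm = 0, rot_deg = 0))
  comp <- c("tx_mm", "ty_mm", "tz_mm", "pitch_deg", "roll_deg", "yaw_deg")
  k <- match(repc$component, comp)
  # 3.5-sigma bound on the recovery error keeps the joint test seed-stable
  expect_true(all(abs(repc$mpe - off[k]) <= 3.5 * spr[k] / sqrt(n)))
})

test_that("shift summaries report descriptive and t-test columns per setup", {
  tab <- simulate_cohort_shifts(cohort_config(n_per_setup = 12, seed = 4))
  s <- summarize_shifts(tab)
  expect_equal(nrow(s), 12L)
  expect_true(all(s$n == 12))
  expect_true(all(s$min <= s$median & s$median <= s$max))
  expect_true(all(s$iqr >= 0))
  expect_true(all(s$p_value >= 0 & s$p_value <= 1))
})
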