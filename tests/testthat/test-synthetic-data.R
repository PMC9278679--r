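test_that("noise-free phantoms are piecewise constant with configured intensities", {
  cfg <- phantom_config(noise_sd = c(0, 0), bias_field_amplitude = 0)
  ph <- generate_skull_phantom(cfg)
  expect_setequal(unique(as.numeric(ph$ct$data)), cfg$ct_intensities)
  expect_setequal(unique(as.numeric(ph$mri$data)), cfg$mri_intensities)
  # shared grid: ground-truth inter-modality transform is the identity
  expect_identical(ph$ct$spacing, ph$mri$spacing)
  expect_identical(ph$ct$origin, ph$mri$origin)
  # inverted contrast: skull bright on CT, dark side on MRI
  expect_gt(cfg$ct_intensities[3], cfg$ct_intensities[2])
  expect_lt(cfg$mri_intensities[3], cfg$mri_intensities[2])
})

test_that("phantom generation is a pure function of its configuration", {
  a <- generate_skull_phantom(phantom_config(seed = 7))
  b <- generate_skull_phantom(phantom_config(seed = 7))
  expect_identical(a$ct$data, b$ct$data)
  expect_identical(a$mri$data, b$mri$data)
  c <- generate_skull_phantom(phantom_config(seed = 8))
  expect_false(identical(a$ct$data, c$ct$data))
})

test_that("voxelized shell volume matches the analytic ellipsoid shell", {
  cfg <- phantom_config(noise_sd = c(0, 0), bias_field_amplitude = 0)
  ph <- generate_skull_phantom(cfg)
  n_shell <- sum(ph$ct$data == cfg$ct_intensities[3])
  expected <- phantom_shell_volume(cfg) / prod(cfg$spacing_mm)
  expect_lt(abs(n_shell / expected - 1), 0.1)
  expect_error(phantom_config(shell_thickness_mm = 60), "semi-axis")
})

test_that("transform injection is identity-safe and invertible within tolerance", {
  ph <- clean_phantom(c(48L, 48L, 48L))
  v <- ph$ct
  expect_identical(inject_transform(v, rigid_transform())$data, v$data)
  sh <- inject_transform(v, rigid_transform(translation = c(v$spacing[1], 0, 0)))
  expect_equal(sh$data[1:47, , ], v$data[2:48, , ])
  # forward-then-inverse double resampling, regression-frozen bounds:
  # pointwise residuals at the sharp shell edge are O(contrast), their mean
  # over the interior is small; a smooth volume stays within 2% everywhere
  ctr <- volume_center(v)
  t <- rigid_transform(c(1.3, -0.7, 2.1), c(1.2, -0.8, 2.0), center = ctr)
  back <- inject_transform(inject_transform(v, t), invert_transform(t))
  interior <- 7:42
  d <- abs(back$data[interior, interior, interior] -
             v$data[interior, interior, interior])
  rng <- diff(range(v$data))
  expect_lt(max(d) / rng, 0.6)
  expect_lt(mean(d) / rng, 0.035)
  sm <- smooth_volume(64L)
  smi <- 9:56
  back2 <- inject_transform(inject_transform(sm, t), invert_transform(t))
  d2 <- abs(back2$data[smi, smi, smi] - sm$data[smi, smi, smi])
  expect_lt(max(d2) / diff(range(sm$data)), 0.02)
})

test_that("degenerate cohort spreads reproduce offsets exactly and seeds reproduce tables", {
  cfg <- cohort_config(n_per_setup = 5,
                       offsets = c(4, 0, 0, 0, 0, 0),
                       spreads = rep(0, 6), seed = 3)
  tab <- simulate_cohort_shifts(cfg)
  expect_equal(nrow(tab), 10L)
  expect_true(all(tab$tx_mm == 4))
  expect_true(all(tab[, c("ty_mm", "tz_mm", "pitch_deg", "roll_deg",
                          "yaw_deg")] == 0))
  cfg2 <- cohort_config(seed = 9)
  expect_identical(simulate_cohort_shifts(cfg2), simulate_cohort_shifts(cfg2))
})

test_that("cohort sample moments converge to configured parameters", {
  cfg <- cohort_config(n_per_setup = 1e4,
                       offsets = c(0, 4, 0, 0, 0, 0),
                       spreads = c(1, 3, 2, 0.5, 0.5, 0.5), seed = 1)
  tab <- simulate_cohort_shifts(cfg)
  comp <- c("tx_mm", "ty_mm", "tz_mm", "pitch_deg", "roll_deg", "yaw_deg")
  for (s in c("C1", "C2")) {
    d <- tab[tab$setup == s, comp]
    means <- colMeans(d)
    sds <- apply(d, 2, sd)
    expect_lt(abs(means[["ty_mm"]] - 4), 0.1)
    # means within 5% of a spread, SDs within 5% relative
    expect_true(all(abs(means - cfg$offsets[[s]]) <= 0.05 * cfg$spreads[[s]]))
    expect_true(all(abs(sds / cfg$spreads[[s]] - 1) < 0.05))
  }
})

test_that("shift tables round-trip through CSV with the declared schema", {
  tab <- simulate_cohort_shifts(cohort_config(n_per_setup = 4, seed = 2))
  f <- withr::local_tempfile(fileext = ".csv")
  write_shift_table(tab, f)
  expect_identical(readLines(f, n = 1),
                   "trial_id,setup,tx_mm,ty_mm,tz_mm,pitch_deg,roll_deg,yaw_deg")
  tab2 <- read_shift_table(f)
  expect_equal(tab2, tab, tolerance = 1e-12)
})
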