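test_that("standard generation respects counts, zero-noise identity and seeding", {
  m <- measurement_model()
  levels <- default_calibration_levels(12)
  std <- make_standards(levels, 3, m, seed = 11)
  expect_equal(nrow(std), 36)
  expect_true(all(std$area_12C >= 0) && all(std$area_13C >= 0))

  m0 <- zero_noise_model()
  std0 <- make_standards(levels, 2, m0, seed = 5)
  expect_equal(std0$observed_ratio,
               nominal_slope(m0) * std0$true_concentration + m0$is_offset,
               tolerance = 1e-12)

  expect_identical(make_standards(levels, 3, m, seed = 7),
                   make_standards(levels, 3, m, seed = 7))
  expect_false(identical(make_standards(levels, 3, m, seed = 7)$observed_ratio,
                         make_standards(levels, 3, m, seed = 8)$observed_ratio))

  expect_error(make_standards(c(1, -1), 3, m), "positive")
  expect_error(make_standards(numeric(0), 3, m), "non-empty")
  expect_error(make_standards(1, 0, m), "n_replicates")
})

test_that("generators restore the caller's RNG state", {
  set.seed(42)
  r1 <- runif(1)
  make_standards(c(1, 2, 3), 2, measurement_model(), seed = 99)
  r2 <- runif(1)
  set.seed(42)
  expect_identical(c(r1, r2), runif(2))
})

test_that("broth samples encode the stated biomass-to-concentration conversion", {
  m <- zero_noise_model()
  br <- make_broth_samples(1.2, 0.20, 3, 3, 0, 0, m, seed = 1)
  expect_equal(nrow(br), 9)
  # 0.20 g/g * 1.2 g/L / 86.09 g/mol = 2.79 mmol/L to 3 s.f.
  expect_equal(unique(br$true_broth_concentration), 2.79, tolerance = 5e-3)
  # all noise off: every injection identical
  expect_equal(length(unique(br$observed_ratio)), 1L)
  expect_error(make_broth_samples(1.2, 0.2, process_cv = -0.1, model = m),
               "non-negative")
  expect_error(make_broth_samples(0, 0.2, model = m), "positive")
  expect_error(make_broth_samples(1.2, 1.0, model = m), "phb_content")
})

test_that("generated ratio scatter matches the error model (Monte Carlo)", {
  m <- measurement_model()
  for (level in c(0.05, 1)) {
    std <- make_standards(level, 10000, m, seed = 21)
    expected_sd <- nominal_slope(m) *
      sqrt(m$sigma_abs^2 + (m$sigma_rel * level)^2)
    expect_equal(sd(std$observed_ratio), expected_sd, tolerance = 0.1)
  }
})

test_that("dilution series: enhancement moves areas, never ratios or concentrations", {
  m0 <- zero_noise_model()
  dil0 <- make_dilution_series(c(0.05, 0.2, 1.0, 3.7), 2.79, 1, model = m0,
                               seed = 1)
  cal <- noise_free_calibration(m0)
  c_base <- invert_calibration(
    compute_ratio(correct_natural_abundance(dil0, m0$f_nat))$ratio,
    cal)$concentration / dil0$volume_ratio
  expect_equal(c_base, rep(2.79, 4), tolerance = 1e-9)

  # enhancement tuned to 1.4x at the top of the range
  m_enh <- measurement_model(sigma_abs = 0, sigma_rel = 0,
                             enhancement_coeff = 0.4 / 3.7)
  dil <- make_dilution_series(c(0.05, 0.2, 1.0, 3.7), 2.79, 1, model = m_enh,
                              seed = 1)
  expect_equal(max(dil$enhancement), 1.4, tolerance = 1e-12)
  ratio_enh <- compute_ratio(correct_natural_abundance(dil, m_enh$f_nat))$ratio
  ratio_plain <- compute_ratio(correct_natural_abundance(dil0, m0$f_nat))$ratio
  expect_equal(ratio_enh, ratio_plain, tolerance = 1e-12)
  # 13C raw area at max load is 40% above the unenhanced counterpart
  expect_equal(dil$area_13C[4] / dil0$area_13C[4], 1.4, tolerance = 1e-6)

  expect_error(make_dilution_series(numeric(0), 2.79, model = m0), "non-empty")
  expect_error(make_dilution_series(c(1, -2), 2.79, model = m0), "positive")
})

test_that("ratios are invariant to common response scaling and enhancement", {
  base <- list(sigma_abs = 0, sigma_rel = 0)
  for (scale in c(0.5, 3)) {
    m1 <- do.call(measurement_model, base)
    m2 <- do.call(measurement_model,
                  c(base, list(response_12C = 5e4 * scale,
                               response_13C = 5e4 * scale,
                               enhancement_coeff = 0.3)))
    s1 <- make_standards(c(0.1, 1, 5), 1, m1, seed = 3)
    s2 <- make_standards(c(0.1, 1, 5), 1, m2, seed = 3)
    r1 <- compute_ratio(correct_natural_abundance(s1, m1$f_nat))$ratio
    r2 <- compute_ratio(correct_natural_abundance(s2, m2$f_nat))$ratio
    expect_equal(r1, r2, tolerance = 1e-12)
  }
})

test_that("rendered SIM traces integrate to the requested area", {
  tr <- render_sim_trace(1e6, retention_time = 300, peak_width_sigma = 2,
                         points_per_peak = 20)
  win <- c(300 - 10, 300 + 10) # +/- 5 sigma
  expect_equal(integrate_peak(tr, win)$area, 1e6, tolerance = 1e-3)

  flat <- render_sim_trace(0, 300, 2)
  expect_true(all(flat$intensities == 0))

  expect_identical(render_sim_trace(1e5, 300, 2, noise_sd = 50, seed = 4),
                   render_sim_trace(1e5, 300, 2, noise_sd = 50, seed = 4))
  expect_error(render_sim_trace(1e5, 300, 2, points_per_peak = 19), "at least 20")
  expect_error(render_sim_trace(-1, 300, 2), "non-negative")
})
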