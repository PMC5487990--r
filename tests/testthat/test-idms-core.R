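test_that("natural-abundance correction subtracts f_nat of the 12C area", {
  pair <- data.frame(sample_id = "a", area_12C = 100000, area_13C = 5000)
  out <- correct_natural_abundance(pair, f_nat = 0.00044)
  expect_equal(out$corrected_area_13C, 4956)
  expect_equal(out$area_12C, 100000)

  expect_identical(correct_natural_abundance(pair, f_nat = 0)$corrected_area_13C,
                   pair$area_13C)

  big <- data.frame(sample_id = "hot", area_12C = 1e7, area_13C = 4000)
  expect_error(correct_natural_abundance(big, f_nat = 0.00044), "hot")
  expect_error(correct_natural_abundance(pair, f_nat = 1), "f_nat")
})

test_that("correction strictly decreases the corrected area as f_nat grows", {
  pair <- data.frame(sample_id = "a", area_12C = 1e5, area_13C = 5e3)
  f <- c(0, 1e-4, 4.4e-4, 1e-3)
  corr <- sapply(f, function(x) {
    correct_natural_abundance(pair, f_nat = x)$corrected_area_13C
  })
  expect_true(all(diff(corr) < 0))
})

test_that("ratio computation divides 12C by corrected 13C area", {
  df <- data.frame(sample_id = c("u", "d"), area_12C = c(4956, 9912),
                   area_13C = c(4956, 4956))
  df$corrected_area_13C <- df$area_13C
  expect_equal(compute_ratio(df)$ratio, c(1, 2))

  zero <- data.frame(sample_id = "z", area_12C = 1, area_13C = 0,
                     corrected_area_13C = 0)
  expect_error(compute_ratio(zero), "no internal standard")
})

test_that("error-model sigma has the stated limits and is monotone", {
  cal <- noise_free_calibration()
  cal$error_model <- c(sigma_abs = 0.0053, sigma_rel = 3e-5)
  expect_equal(error_model_sigma(0, cal), cal$slope * 0.0053)

  cal_rel0 <- cal
  cal_rel0$error_model <- c(sigma_abs = 0.0053, sigma_rel = 0)
  s <- error_model_sigma(c(0, 1, 5, 11), cal_rel0)
  expect_true(all(s == s[1]))

  grid <- seq(0, 11, length.out = 200)
  expect_true(all(diff(error_model_sigma(grid, cal)) >= 0))
  expect_error(error_model_sigma(-1, cal), "non-negative")
})

test_that("noise-free calibration recovers the generating slope and offset", {
  cal <- noise_free_calibration(zero_noise_model())
  expect_equal(cal$slope, 1 / (9.3 * 0.2), tolerance = 1e-9)
  expect_equal(cal$intercept, 0.01, tolerance = 1e-9)
  expect_true(all(eigen(cal$parameter_covariance)$values >= 0))
})

test_that("weighted fit equals the closed-form normal-equations oracle", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    conc <- sort(runif(n, 0.01, 11))
    ratio <- 0.5 * conc + 0.01 + rnorm(n, 0, 0.003)
    sa <- runif(1, 1e-3, 1e-2)
    sr <- runif(1, 0, 1e-3)
    fit <- fit_calibration(data.frame(concentration = conc, ratio = ratio),
                           error_model = c(sigma_abs = sa, sigma_rel = sr))
    oracle <- wls_oracle(conc, ratio, sa, sr)
    expect_equal(fit$slope, oracle$slope, tolerance = 1e-10)
    expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-10)
  }
})

test_that("calibration is linear in the ratios and validates its inputs", {
  std <- make_standards(c(0.1, 1, 5), 2, zero_noise_model(), seed = 1)
  fit1 <- fit_calibration(std, default_error_model)
  std_k <- std
  std_k$observed_ratio <- 3 * std$observed_ratio
  fit3 <- fit_calibration(std_k, default_error_model)
  expect_equal(fit3$slope, 3 * fit1$slope, tolerance = 1e-10)
  expect_equal(fit3$intercept, 3 * fit1$intercept, tolerance = 1e-10)

  expect_error(fit_calibration(std[std$true_concentration < 1, ],
                               default_error_model), "3 distinct")
  expect_error(fit_calibration(std, c(sigma_abs = 0, sigma_rel = 0)),
               "weights")
  std_bad <- std
  std_bad$observed_ratio[1] <- NaN
  expect_error(fit_calibration(std_bad, default_error_model), "non-finite")
})

test_that("inverse prediction round-trips and flags sub-intercept ratios", {
  cal <- build_calibration(seed = 3)
  for (c_true in c(0.01, 1, 10)) {
    r <- cal$slope * c_true + cal$intercept
    expect_equal(invert_calibration(r, cal)$concentration, c_true,
                 tolerance = 1e-12)
  }
  at0 <- invert_calibration(cal$intercept, cal)
  expect_equal(at0$concentration, 0)
  below <- invert_calibration(cal$intercept - 0.01, cal)
  expect_equal(below$flag, "below_calibration")
})

test_that("propagated inversion SE matches Monte-Carlo scatter", {
  m <- measurement_model()
  cal <- build_calibration(m, seed = 5)
  n <- 5000
  set.seed(9)
  sig <- nominal_slope(m) * sqrt(m$sigma_abs^2 + (m$sigma_rel * 1)^2)
  ratios <- nominal_slope(m) * 1 + m$is_offset + rnorm(n, 0, sig)
  inv <- invert_calibration(ratios, cal)
  expect_equal(sd(inv$concentration), mean(inv$se), tolerance = 0.15)
})

test_that("LOD scales with noise and sits in a sane range", {
  std <- make_standards(default_calibration_levels(), 3, measurement_model(),
                        seed = 13)
  cal1 <- fit_calibration(std, c(sigma_abs = 0.0053, sigma_rel = 3e-5))
  cal2 <- fit_calibration(std, c(sigma_abs = 2 * 0.0053, sigma_rel = 2 * 3e-5))
  expect_equal(lod(cal2), 2 * lod(cal1), tolerance = 1e-9)
  expect_equal(lod(cal1, k = 0), 0)
  # order-of-magnitude sanity: below 10x the lowest calibration level
  expect_lt(lod(cal1), 0.001 * 10)
})

test_that("IS suspension concentration is recovered against the 12C response", {
  m0 <- zero_noise_model()
  std0 <- make_standards(default_calibration_levels(), 1, m0, seed = 1)
  est0 <- estimate_is_concentration(make_is_runs(3, m0, seed = 2),
                                    fit_area_response(std0))
  expect_equal(est0, 9.3, tolerance = 1e-9)

  # slope-shortcut oracle: c_IS read back from the ratio-calibration slope
  cal0 <- noise_free_calibration(m0)
  expect_equal(is_concentration_from_slope(cal0), 9.3, tolerance = 1e-9)

  m <- measurement_model()
  ests <- sapply(1:100, function(s) {
    std <- make_standards(default_calibration_levels(), 3, m, seed = 1000 + s)
    estimate_is_concentration(make_is_runs(3, m, seed = 2000 + s),
                              fit_area_response(std))
  })
  expect_equal(mean(ests), 9.3, tolerance = 0.01)

  bad <- data.frame(sample_id = "x", area_12C = 0, area_13C = 0)
  expect_error(estimate_is_concentration(bad, fit_area_response(std0)),
               "zero 13C")
})

test_that("zero-noise full chain returns the generating parameters", {
  m0 <- zero_noise_model()
  cal <- noise_free_calibration(m0)
  expect_equal(cal$slope, nominal_slope(m0), tolerance = 1e-9)

  br <- make_broth_samples(1.2, 0.20, 3, 3, 0, 0, m0, seed = 1)
  res <- quantify_samples(br, cal, cdw = 1.2, f_nat = m0$f_nat)
  c_true <- 1.2 * 0.20 / 86.09 * 1000
  expect_equal(res$broth_mmol_L, rep(c_true, 9), tolerance = 1e-6)
  expect_equal(res$phb_content_pct, rep(20, 9), tolerance = 1e-6)
})
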