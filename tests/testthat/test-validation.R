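sim_nested <- function(seed, injection_cv, process_cv, n_cultures = 2) {
  m <- measurement_model()
  cal <- build_calibration(m, seed = 500)
  broth <- do.call(rbind, lapply(seq_len(n_cultures), function(k) {
    make_broth_samples(1.2, 0.20, 3, 3, process_cv, injection_cv, m,
                       seed = seed * 10 + k, culture = sprintf("c%d", k))
  }))
  quantify_samples(broth, cal, cdw = 1.2, f_nat = m$f_nat)
}

test_that("pooled RSDs reproduce hand-computed and degenerate cases", {
  df <- data.frame(culture = "A",
                   process_replicate = rep(1:2, each = 3),
                   concentration_mmol_L = rep(c(100, 101, 102), 2))
  rep_ <- pooled_rsd(df)
  expect_equal(rep_$analytical_rsd, 100 * 1 / 101, tolerance = 1e-9)
  expect_equal(rep_$flag, "technical_below_analytical")

  same <- df
  same$concentration_mmol_L <- 5
  expect_equal(pooled_rsd(same)$analytical_rsd, 0)
  expect_equal(pooled_rsd(same)$technical_rsd, 0)

  expect_error(pooled_rsd(df[c(1, 4), ]), "2 injections")
  one_sample <- df[df$process_replicate == 1, ]
  expect_error(pooled_rsd(one_sample), "2 processed samples")
})

test_that("pooled RSD estimator tracks the generating CVs", {
  rsds <- t(sapply(1:100, function(s) {
    r <- pooled_rsd(sim_nested(s, injection_cv = 0.015, process_cv = 0.012))
    c(r$analytical_rsd, r$technical_rsd)
  }))
  expect_equal(mean(rsds[, 1]), 1.5, tolerance = 0.1)
  # independent process and injection noise combine in quadrature
  expect_equal(mean(rsds[, 2]), sqrt(1.2^2 + 1.5^2), tolerance = 0.1)
})

test_that("standard-addition recovery is exact without noise and unbiased with it", {
  m0 <- zero_noise_model()
  cal0 <- noise_free_calibration(m0)
  exp0 <- make_recovery_experiment(2.3, 2.3, model = m0, seed = 1)
  rec0 <- standard_addition_recovery(exp0, cal0)
  expect_equal(rec0$recoveries, rep(100, 6), tolerance = 1e-9)

  m <- measurement_model()
  cal <- build_calibration(m, seed = 2)
  exp1 <- make_recovery_experiment(2.3, 2.3, model = m, seed = 42)
  rec1 <- standard_addition_recovery(exp1, cal)
  expect_true(all(abs(rec1$by_culture$mean_recovery - 100) < 5))
  expect_match(rec1$decision, "retained")

  # deliberate 10% suppression of the spiked signal is detected
  exp_bias <- exp1
  exp_bias$ratio_spiked <- exp_bias$ratio_base +
    0.9 * (exp_bias$ratio_spiked - exp_bias$ratio_base)
  rec_bias <- standard_addition_recovery(exp_bias, cal)
  expect_equal(rec_bias$mean, 90, tolerance = 0.05)
  expect_match(rec_bias$decision, "rejected")

  expect_error(standard_addition_recovery(exp1[, -1 * 4], cal), "need columns")
})

test_that("recovery estimator is unbiased over many seeds", {
  m <- measurement_model()
  cal <- build_calibration(m, seed = 3)
  means <- sapply(1:1000, function(s) {
    standard_addition_recovery(
      make_recovery_experiment(2.3, 2.3, model = m, seed = 5000 + s), cal)$mean
  })
  expect_equal(mean(means), 100, tolerance = 0.005)
})

test_that("Welch comparison from summary statistics matches hand and oracle results", {
  res <- method_comparison_ttest(14.4, 1.6, 3, 12.7, 2.0, 3)
  expect_equal(res$t_statistic, 1.149, tolerance = 1e-3)
  expect_equal(res$decision, "no significant difference")

  same <- method_comparison_ttest(10, 1, 5, 10, 1, 5)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)

  expect_error(method_comparison_ttest(1, 1, 1, 2, 1, 3), "n >= 2")
  expect_error(method_comparison_ttest(1, 0, 3, 2, 1, 3), "positive")

  # qualitative agreement with a label-permutation oracle on raw groups
  set.seed(55)
  for (i in 1:20) {
    n <- sample(5:10, 2, replace = TRUE)
    shift <- sample(c(0, 4), 1) # null or a 4-SD effect
    a <- rnorm(n[1], 0, 1)
    b <- rnorm(n[2], shift, 1.3)
    welch <- method_comparison_ttest(mean(a), sd(a), n[1],
                                     mean(b), sd(b), n[2])
    obs <- abs(mean(a) - mean(b))
    pooled <- c(a, b)
    perm <- replicate(500, {
      idx <- sample(length(pooled), n[1])
      abs(mean(pooled[idx]) - mean(pooled[-idx]))
    })
    p_perm <- mean(perm >= obs)
    expect_equal(welch$p_value <= 0.05, p_perm <= 0.05)
  }
})

test_that("matrix-effect test accepts invariant series and catches trends", {
  m0 <- zero_noise_model()
  cal0 <- noise_free_calibration(m0)
  dil0 <- make_dilution_series(c(0.05, 0.2, 1, 3.7), 2.79, 3, model = m0,
                               seed = 1)
  res0 <- matrix_effect_test(dil0, cal0, f_nat = m0$f_nat)
  expect_lt(abs(res0$chi_square_delta), 1e-9)
  expect_equal(res0$conclusion, "no matrix effect")

  m <- measurement_model()
  cal <- build_calibration(m, seed = 7)
  verdicts <- sapply(1:50, function(s) {
    dil <- make_dilution_series(c(0.05, 0.2, 0.5, 1, 2, 3.7), 2.79, 3,
                                model = m, seed = 800 + s)
    matrix_effect_test(dil, cal, f_nat = m$f_nat)$conclusion
  })
  expect_gte(mean(verdicts == "no matrix effect"), 0.9)

  trended <- sapply(1:50, function(s) {
    dil <- make_dilution_series(c(0.05, 0.2, 0.5, 1, 2, 3.7), 2.79, 3,
                                trend_coeff = 0.2, model = m, seed = 900 + s)
    matrix_effect_test(dil, cal, f_nat = m$f_nat)$conclusion
  })
  expect_gte(mean(trended == "matrix effect"), 0.9)

  expect_error(matrix_effect_test(dil0[dil0$volume_ratio < 1, ], cal0),
               "4 distinct")
  narrow <- make_dilution_series(c(1, 1.5, 2, 3), 2.79, 1, model = m0, seed = 1)
  expect_warning(matrix_effect_test(narrow, cal0, f_nat = m0$f_nat),
                 "order of magnitude")
})

test_that("matrix-effect test holds its nominal type-I error under H0", {
  m <- measurement_model()
  cal <- build_calibration(m, seed = 12)
  rejections <- sapply(1:1000, function(s) {
    dil <- make_dilution_series(c(0.05, 0.2, 0.5, 1, 2, 3.7), 2.79, 3,
                                model = m, seed = 10000 + s)
    matrix_effect_test(dil, cal, f_nat = m$f_nat)$p_value <= 0.05
  })
  # binomial 99% band around 0.05 at n = 1000 is about +/- 0.018
  expect_lt(abs(mean(rejections) - 0.05), 0.02)
})

test_that("area response report shows enhancement in areas but not in concentration", {
  # f_nat = 0 so the raw 13C area carries no leak from the growing 12C peak
  m0 <- zero_noise_model(f_nat = 0)
  cal0 <- noise_free_calibration(m0)
  dil_flat <- make_dilution_series(c(0.05, 0.2, 1, 3.7), 2.79, 2, model = m0,
                                   seed = 1)
  rep_flat <- area_response_report(dil_flat, cal0, f_nat = m0$f_nat)
  expect_equal(rep_flat$fold_change, rep(1, 4), tolerance = 1e-12)

  m_enh <- measurement_model(sigma_abs = 0, sigma_rel = 0, f_nat = 0)
  dil <- make_dilution_series(c(0.05, 0.2, 1, 3.7), 2.79, 2, model = m_enh,
                              seed = 1)
  cal <- noise_free_calibration(m_enh)
  rep_enh <- area_response_report(dil, cal, f_nat = m_enh$f_nat)
  expect_equal(max(rep_enh$fold_change),
               (1 + m_enh$enhancement_coeff * 3.7) /
                 (1 + m_enh$enhancement_coeff * 0.05),
               tolerance = 1e-9)
  expect_true(all(diff(rep_enh$fold_change) > 0))
  expect_lt(attr(rep_enh, "concentration_spread_rel"), 1e-9)
})
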