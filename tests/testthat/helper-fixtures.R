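# Shared fixtures: a noise-free model for exactness checks and a default
# calibration builder.

zero_noise_model <- function(...) {
  measurement_model(sigma_abs = 0, sigma_rel = 0, enhancement_coeff = 0, ...)
}

default_error_model <- c(sigma_abs = 0.0053, sigma_rel = 3e-5)

# standards + weighted calibration in one step
build_calibration <- function(model = measurement_model(), seed = 1,
                              n_replicates = 3,
                              levels = default_calibration_levels()) {
  std <- make_standards(levels, n_replicates, model, seed = seed)
  fit_calibration(std, error_model = c(sigma_abs = model$sigma_abs,
                                       sigma_rel = model$sigma_rel))
}

# noise-free calibration has exactly the nominal slope and is_offset intercept;
# a tiny error model is still needed for the WLS weights
noise_free_calibration <- function(model = zero_noise_model()) {
  std <- make_standards(default_calibration_levels(), 1, model, seed = 1)
  fit_calibration(std, error_model = c(sigma_abs = 1e-6, sigma_rel = 0))
}

# closed-form weighted normal equations, independent of fit_calibration():
# unweighted moment-formula slope feeds the same one-step weight map
wls_oracle <- function(conc, ratio, sigma_abs, sigma_rel) {
  slope0 <- sum((conc - mean(conc)) * (ratio - mean(ratio))) /
    sum((conc - mean(conc))^2)
  w <- 1 / (slope0^2 * (sigma_abs^2 + (sigma_rel * conc)^2))
  sw <- sum(w); swx <- sum(w * conc); swy <- sum(w * ratio)
  swxx <- sum(w * conc^2); swxy <- sum(w * conc * ratio)
  det <- sw * swxx - swx^2
  list(slope = (sw * swxy - swx * swy) / det,
       intercept = (swxx * swy - swx * swxy) / det)
}
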