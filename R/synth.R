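# Synthetic-data generators: calibration standards, broth samples, spiked
# pairs, dilution series, IS-alone runs, and rendered SIM traces. Every
# generator takes one explicit seed and restores the caller's RNG state.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
      stop("seed must be a single finite number or NULL")
    }
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# SD of a measured ratio at true concentration c, in ratio units, using the
# noise-free slope of the generating model.
ratio_sigma_true <- function(concentration, model) {
  nominal_slope(model) *
    sqrt(model$sigma_abs^2 + (model$sigma_rel * concentration)^2)
}

# Raw channel areas consistent with an observed (corrected-area) ratio.
# The corrected 13C area is response_13C * n13 * enhancement; the raw 13C
# area additionally carries the natural-abundance leak f_nat * area_12C, so
# that correct_natural_abundance() recovers exactly the corrected area.
areas_from_ratio <- function(observed_ratio, model, enhancement = 1) {
  a13_corrected <- model$response_13C * is_amount(model) * enhancement
  a12 <- observed_ratio * a13_corrected
  list(area_12C = a12, area_13C = a13_corrected + model$f_nat * a12)
}

#' Log-spaced calibration levels spanning the method's working range
#'
#' @param n number of levels.
#' @param lower,upper range limits, mmol/L (default 0.001 to 11, four orders
#'   of magnitude).
#' @return Numeric vector of concentrations, mmol/L.
#' @export
default_calibration_levels <- function(n = 12, lower = 0.001, upper = 11) {
  exp(seq(log(lower), log(upper), length.out = n))
}

#' Simulate calibration standards measured against the labelled IS
#'
#' Each standard carries `level * sample_volume` nmol of unlabelled monomer
#' plus the fixed IS amount. The noise-free ratio is
#' `nominal_slope(model) * level + is_offset`; heteroscedastic Gaussian
#' noise with SD [ratio_sigma_true] is added, and raw channel areas
#' consistent with the noisy ratio (including the natural-abundance leak
#' into the 13C channel) are rendered from the response factors.
#'
#' @param levels standard concentrations, mmol/L, all positive.
#' @param n_replicates injections per level.
#' @param model a [measurement_model()].
#' @param seed RNG seed for this call.
#' @return A data.frame with one row per injection: `sample_id`,
#'   `true_concentration`, `replicate_index`, `area_12C`, `area_13C`,
#'   `observed_ratio`.
#' @examples
#' std <- make_standards(default_calibration_levels(), 3,
#'                       measurement_model(), seed = 1)
#' @export
make_standards <- function(levels, n_replicates = 3, model = measurement_model(),
                           seed = NULL) {
  stopifnot(inherits(model, "measurement_model"))
  if (length(levels) == 0L) stop("make_standards: 'levels' must be non-empty")
  if (any(!is.finite(levels)) || any(levels <= 0)) {
    stop("make_standards: all levels must be positive and finite")
  }
  if (n_replicates < 1) stop("make_standards: n_replicates must be >= 1")
  with_seed(seed, {
    grid <- expand.grid(replicate_index = seq_len(n_replicates),
                        true_concentration = levels)
    grid <- grid[order(grid$true_concentration, grid$replicate_index), ]
    r_true <- nominal_slope(model) * grid$true_concentration + model$is_offset
    noise <- stats::rnorm(nrow(grid), 0,
                          ratio_sigma_true(grid$true_concentration, model))
    obs <- r_true + noise
    areas <- areas_from_ratio(obs, model)
    data.frame(
      sample_id = sprintf("std_%02d_r%d",
                          match(grid$true_concentration, sort(unique(levels))),
                          grid$replicate_index),
      true_concentration = grid$true_concentration,
      replicate_index = grid$replicate_index,
      area_12C = areas$area_12C,
      area_13C = areas$area_13C,
      observed_ratio = obs,
      row.names = NULL
    )
  })
}

#' Simulate replicate broth samples from a PHB-producing culture
#'
#' The true monomer concentration in broth follows from biomass and content:
#' `cdw * phb_content / monomer_mass * 1000` mmol/L. Processing noise
#' (centrifugation, resuspension, derivatization) multiplies the analyte
#' amount once per processed replicate; injection noise multiplies it once
#' per injection; the heteroscedastic ratio error model is added on top of
#' every injection. Noise CVs are coefficients of variation as fractions
#' (0.015 = 1.5\%).
#'
#' @param cdw cell dry weight, g/L.
#' @param phb_content true PHB content, g per g CDW, in `[0, 1)`.
#' @param n_process_replicates independently processed broth samples.
#' @param n_injections injections per processed sample.
#' @param process_cv,injection_cv multiplicative noise CVs (fractions).
#' @param model a [measurement_model()].
#' @param seed RNG seed.
#' @param culture label carried into the output.
#' @return A data.frame with one row per injection: `sample_id`, `culture`,
#'   `process_replicate`, `injection`, `true_broth_concentration` (mmol/L),
#'   `area_12C`, `area_13C`, `observed_ratio`.
#' @export
make_broth_samples <- function(cdw, phb_content,
                               n_process_replicates = 3, n_injections = 3,
                               process_cv = 0, injection_cv = 0,
                               model = measurement_model(), seed = NULL,
                               culture = "C1") {
  stopifnot(inherits(model, "measurement_model"))
  if (cdw <= 0) stop("make_broth_samples: cdw must be positive")
  if (phb_content < 0 || phb_content >= 1) {
    stop("make_broth_samples: phb_content must be in [0, 1)")
  }
  if (process_cv < 0 || injection_cv < 0) {
    stop("make_broth_samples: noise CVs must be non-negative")
  }
  if (n_process_replicates < 1 || n_injections < 1) {
    stop("make_broth_samples: replicate counts must be >= 1")
  }
  c_broth <- cdw * phb_content / model$monomer_mass * 1000
  with_seed(seed, {
    rows <- vector("list", n_process_replicates)
    for (j in seq_len(n_process_replicates)) {
      f_proc <- 1 + stats::rnorm(1, 0, process_cv)
      g_inj <- 1 + stats::rnorm(n_injections, 0, injection_cv)
      c_eff <- c_broth * f_proc * g_inj
      obs <- nominal_slope(model) * c_eff + model$is_offset +
        stats::rnorm(n_injections, 0, ratio_sigma_true(c_eff, model))
      areas <- areas_from_ratio(obs, model)
      rows[[j]] <- data.frame(
        sample_id = sprintf("%s_s%d_i%d", culture, j, seq_len(n_injections)),
        culture = culture,
        process_replicate = j,
        injection = seq_len(n_injections),
        true_broth_concentration = c_broth,
        area_12C = areas$area_12C,
        area_13C = areas$area_13C,
        observed_ratio = obs,
        row.names = NULL
      )
    }
    do.call(rbind, rows)
  })
}

#' Simulate a paired standard-addition (spike) experiment
#'
#' For each sample, a base aliquot and a spiked aliquot (base + a known
#' monomer concentration) are measured; both carry the same processing
#' factor, and each measurement gets its own error-model ratio noise. With
#' all noise off, the ratio increment over the spike equals exactly the
#' calibration-predicted net ratio of the spike concentration, so recovery
#' is 100\% by construction.
#'
#' @param base_concentration prep-equivalent base concentration, mmol/L.
#' @param spike_concentration spike added, mmol/L, positive.
#' @param n_cultures,n_samples cultures and samples per culture.
#' @param process_cv multiplicative processing noise CV (fraction).
#' @param model a [measurement_model()].
#' @param seed RNG seed.
#' @return A data.frame with `sample_id`, `culture`, `spike_mmol_L`,
#'   `ratio_base`, `ratio_spiked`.
#' @export
make_recovery_experiment <- function(base_concentration, spike_concentration,
                                     n_cultures = 2, n_samples = 3,
                                     process_cv = 0,
                                     model = measurement_model(),
                                     seed = NULL) {
  stopifnot(inherits(model, "measurement_model"))
  if (spike_concentration <= 0) {
    stop("make_recovery_experiment: spike_concentration must be positive")
  }
  if (base_concentration < 0) {
    stop("make_recovery_experiment: base_concentration must be non-negative")
  }
  slope <- nominal_slope(model)
  with_seed(seed, {
    grid <- expand.grid(sample = seq_len(n_samples),
                        culture = seq_len(n_cultures))
    n <- nrow(grid)
    f_proc <- 1 + stats::rnorm(n, 0, process_cv)
    c_base <- base_concentration * f_proc
    c_spiked <- c_base + spike_concentration
    ratio_base <- slope * c_base + model$is_offset +
      stats::rnorm(n, 0, ratio_sigma_true(c_base, model))
    ratio_spiked <- slope * c_spiked + model$is_offset +
      stats::rnorm(n, 0, ratio_sigma_true(c_spiked, model))
    data.frame(
      sample_id = sprintf("cult%d_s%d", grid$culture, grid$sample),
      culture = sprintf("cult%d", grid$culture),
      spike_mmol_L = spike_concentration,
      ratio_base = ratio_base,
      ratio_spiked = ratio_spiked,
      row.names = NULL
    )
  })
}

#' Simulate a matrix-dilution series at varying 12C/13C volume ratios
#'
#' Each level scales the broth volume by `volume_ratio` relative to the
#' regular prep while the IS volume stays fixed, so the noise-free measured
#' ratio scales proportionally. Raw areas of both channels are multiplied by
#' the matrix-enhancement factor `1 + enhancement_coeff * volume_ratio`,
#' which cancels from the ratio. `trend_coeff` injects a genuine matrix bias
#' on the ratio itself (fractional bias per unit volume ratio) and is zero
#' for matrix-free data; it exists to construct positive controls for the
#' matrix-effect test.
#'
#' @param volume_ratios broth-to-IS volume ratios relative to the regular
#'   prep, all positive.
#' @param base_concentration true broth concentration of the undiluted
#'   sample, mmol/L.
#' @param n_replicates measurements per level.
#' @param trend_coeff injected ratio bias per unit volume ratio (fraction).
#' @param model a [measurement_model()].
#' @param seed RNG seed.
#' @return A data.frame with `sample_id`, `volume_ratio`, `replicate`,
#'   `true_base_concentration`, `enhancement`, `area_12C`, `area_13C`,
#'   `observed_ratio`.
#' @export
make_dilution_series <- function(volume_ratios, base_concentration,
                                 n_replicates = 3, trend_coeff = 0,
                                 model = measurement_model(), seed = NULL) {
  stopifnot(inherits(model, "measurement_model"))
  if (length(volume_ratios) == 0L) {
    stop("make_dilution_series: 'volume_ratios' must be non-empty")
  }
  if (any(volume_ratios <= 0)) {
    stop("make_dilution_series: all volume ratios must be positive")
  }
  if (base_concentration < 0) {
    stop("make_dilution_series: base_concentration must be non-negative")
  }
  slope <- nominal_slope(model)
  with_seed(seed, {
    rows <- lapply(seq_along(volume_ratios), function(i) {
      d <- volume_ratios[i]
      c_prep <- base_concentration * d * (1 + trend_coeff * d)
      obs <- slope * c_prep + model$is_offset +
        stats::rnorm(n_replicates, 0, ratio_sigma_true(c_prep, model))
      enh <- 1 + model$enhancement_coeff * d
      areas <- areas_from_ratio(obs, model, enhancement = enh)
      data.frame(
        sample_id = sprintf("dil_%02d_r%d", i, seq_len(n_replicates)),
        volume_ratio = d,
        replicate = seq_len(n_replicates),
        true_base_concentration = base_concentration,
        enhancement = enh,
        area_12C = areas$area_12C,
        area_13C = areas$area_13C,
        observed_ratio = obs,
        row.names = NULL
      )
    })
    do.call(rbind, rows)
  })
}

#' Simulate measurements of the IS suspension run alone
#'
#' The IS aliquot contributes `is_concentration * is_volume` nmol of
#' labelled monomer, i.e. a prep-equivalent concentration of
#' `is_amount(model) / sample_volume` mmol/L; the error model perturbs that
#' equivalent concentration. The 12C channel carries only the residual
#' unlabelled signal of the IS (`is_offset` in ratio units), and the raw
#' 13C area includes the natural-abundance leak from it.
#'
#' @param n number of injections.
#' @param model a [measurement_model()].
#' @param seed RNG seed.
#' @return A data.frame with `sample_id`, `area_12C`, `area_13C`.
#' @export
make_is_runs <- function(n = 3, model = measurement_model(), seed = NULL) {
  stopifnot(inherits(model, "measurement_model"))
  if (n < 1) stop("make_is_runs: n must be >= 1")
  c_eq <- is_amount(model) / model$sample_volume
  with_seed(seed, {
    c_obs <- c_eq + stats::rnorm(n, 0, sqrt(model$sigma_abs^2 +
                                              (model$sigma_rel * c_eq)^2))
    a13_corrected <- model$response_13C * c_obs * model$sample_volume
    a12 <- model$is_offset * a13_corrected
    data.frame(
      sample_id = sprintf("is_run_%d", seq_len(n)),
      area_12C = a12,
      area_13C = a13_corrected + model$f_nat * a12,
      row.names = NULL
    )
  })
}

#' Render a SIM chromatogram trace with a single Gaussian peak
#'
#' The trace covers retention_time +/- 8 peak sigmas with a sampling
#' interval of `6 * peak_width_sigma / points_per_peak`, so at least
#' `points_per_peak` points fall across the central +/- 3 sigma of the
#' peak. In the noise-free, zero-baseline case the trapezoidal integral
#' over +/- 5 sigma recovers `area` to well within 0.1\%.
#'
#' @param area true peak area, counts x seconds equivalent (non-negative).
#' @param retention_time peak apex time, s.
#' @param peak_width_sigma Gaussian sigma of the peak, s.
#' @param baseline constant baseline intensity, counts.
#' @param noise_sd SD of additive white noise, counts.
#' @param points_per_peak sampling density; at least 20.
#' @param seed RNG seed.
#' @param channel label, "12C" or "13C".
#' @return An object of class `sim_trace`: list with `channel`, `times`,
#'   `intensities`, `points_per_peak`.
#' @export
render_sim_trace <- function(area, retention_time = 300, peak_width_sigma = 2,
                             baseline = 0, noise_sd = 0, points_per_peak = 20,
                             seed = NULL, channel = "12C") {
  if (area < 0) stop("render_sim_trace: area must be non-negative")
  if (points_per_peak < 20) {
    stop("render_sim_trace: points_per_peak must be at least 20")
  }
  if (peak_width_sigma <= 0) {
    stop("render_sim_trace: peak_width_sigma must be positive")
  }
  dt <- 6 * peak_width_sigma / points_per_peak
  times <- seq(retention_time - 8 * peak_width_sigma,
               retention_time + 8 * peak_width_sigma, by = dt)
  signal <- area * stats::dnorm(times, retention_time, peak_width_sigma)
  with_seed(seed, {
    noise <- if (noise_sd > 0) stats::rnorm(length(times), 0, noise_sd) else 0
    intensities <- pmax(signal + baseline + noise, 0)
    structure(list(channel = channel, times = times,
                   intensities = intensities,
                   points_per_peak = as.integer(points_per_peak)),
              class = "sim_trace")
  })
}

#' @export
print.sim_trace <- function(x, ...) {
  cat(sprintf("SIM trace [%s]: %d points, %.1f-%.1f s, max %.3g counts\n",
              x$channel, length(x$times), min(x$times), max(x$times),
              max(x$intensities)))
  invisible(x)
}
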