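#' Measurement model for GC-IDMS quantification of PHB monomer
#'
#' Bundles every parameter of the measurement process: the internal-standard
#' (IS) suspension, prep volumes, the heteroscedastic error model of the
#' measured \eqn{^{12}C/^{13}C} ratio, detector response factors, the
#' natural-abundance cross-channel interference, and the multiplicative
#' matrix-enhancement coefficient. All concentrations are mmol/L of the
#' monomer unit (PHB)1, all volumes are microlitres, so amounts
#' (concentration x volume) come out in nmol.
#'
#' The error model states the standard deviation of a measured ratio at true
#' concentration c, expressed in concentration units:
#' \deqn{\sigma_c(c) = \sqrt{\sigma_{abs}^2 + (\sigma_{rel} c)^2}}
#' and maps to ratio units through the calibration slope. The defaults
#' (0.0053 mmol/L absolute, 3e-5 relative) are the fitted error model of the
#' method this package implements; swap the two via the arguments if the
#' opposite reading of the pair is wanted.
#'
#' @param is_concentration IS suspension monomer concentration, mmol/L.
#' @param is_volume IS volume added per sample, uL.
#' @param sample_volume broth (or standard) volume per sample, uL.
#' @param sigma_abs absolute error of the ratio error model, mmol/L.
#' @param sigma_rel relative error of the ratio error model, dimensionless.
#' @param f_nat natural-abundance fraction of the unlabelled peak that leaks
#'   into the labelled channel (default 0.044\%).
#' @param response_12C,response_13C detector response, area counts per nmol,
#'   for each SIM channel. Equal by default (equal molar response of
#'   labelled and unlabelled analyte).
#' @param is_offset residual unlabelled signal of the IS, expressed in ratio
#'   units; it is absorbed by the intercept of the calibration line.
#' @param enhancement_coeff multiplicative matrix enhancement of raw peak
#'   areas per unit matrix load (matrix load = the 12C/13C volume ratio of
#'   the prep). The default reproduces a 40\% enhancement at a volume ratio
#'   of 3.7. Both channels are scaled equally, so ratios are unaffected.
#' @param monomer_mass molar mass of the PHB repeat unit, g/mol.
#'
#' @return An object of class `measurement_model` (a validated list).
#' @examples
#' m <- measurement_model()
#' nominal_slope(m)  # ratio units per mmol/L
#' @export
measurement_model <- function(is_concentration = 9.3,
                              is_volume = 200,
                              sample_volume = 1000,
                              sigma_abs = 0.0053,
                              sigma_rel = 3e-5,
                              f_nat = 4.4e-4,
                              response_12C = 5e4,
                              response_13C = 5e4,
                              is_offset = 0.01,
                              enhancement_coeff = 0.4 / 3.7,
                              monomer_mass = 86.09) {
  m <- list(
    is_concentration = is_concentration,
    is_volume = is_volume,
    sample_volume = sample_volume,
    sigma_abs = sigma_abs,
    sigma_rel = sigma_rel,
    f_nat = f_nat,
    response_12C = response_12C,
    response_13C = response_13C,
    is_offset = is_offset,
    enhancement_coeff = enhancement_coeff,
    monomer_mass = monomer_mass
  )
  for (nm in names(m)) {
    v <- m[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("measurement_model: '", nm, "' must be a single finite number")
    }
  }
  if (is_concentration <= 0 || is_volume <= 0 || sample_volume <= 0) {
    stop("measurement_model: volumes and concentrations must be strictly positive")
  }
  if (f_nat < 0 || f_nat >= 1) stop("measurement_model: f_nat must be in [0, 1)")
  if (sigma_abs < 0 || sigma_rel < 0) {
    stop("measurement_model: error-model sigmas must be non-negative")
  }
  if (response_12C <= 0 || response_13C <= 0) {
    stop("measurement_model: response factors must be positive")
  }
  if (is_offset < 0) stop("measurement_model: is_offset must be non-negative")
  if (monomer_mass <= 0) stop("measurement_model: monomer_mass must be positive")
  structure(m, class = "measurement_model")
}

#' @export
print.measurement_model <- function(x, ...) {
  cat("GC-IDMS measurement model\n")
  cat(sprintf("  IS: %.3g mmol/L, %.0f uL per %.0f uL sample\n",
              x$is_concentration, x$is_volume, x$sample_volume))
  cat(sprintf("  error model: sigma_abs %.4g mmol/L, sigma_rel %.3g\n",
              x$sigma_abs, x$sigma_rel))
  cat(sprintf("  f_nat %.3g, is_offset %.3g (ratio), enhancement %.3g per unit load\n",
              x$f_nat, x$is_offset, x$enhancement_coeff))
  invisible(x)
}

#' Sample preparation volumes
#'
#' Records the volumes of one prepared injection vial: broth (or standard),
#' IS suspension, and make-up water. The water volume does not enter any
#' amount calculation (everything is freeze-dried before derivatization) but
#' is carried for provenance.
#'
#' @param broth_volume broth or standard volume, uL.
#' @param is_volume IS suspension volume, uL.
#' @param water_volume make-up water volume, uL.
#' @return An object of class `sample_prep`.
#' @export
sample_prep <- function(broth_volume = 1000, is_volume = 200,
                        water_volume = 500) {
  if (broth_volume <= 0) stop("sample_prep: broth_volume must be positive")
  if (is_volume < 0 || water_volume < 0) {
    stop("sample_prep: volumes must be non-negative")
  }
  structure(list(broth_volume = broth_volume, is_volume = is_volume,
                 water_volume = water_volume),
            class = "sample_prep")
}

#' Noise-free calibration slope implied by a measurement model
#'
#' The measured ratio of a standard at concentration c (prep volume V_std)
#' against n13 = c_IS * V_IS nmol of internal standard is
#' R = c * V_std / (c_IS * V_IS) + is_offset, so the slope in ratio units
#' per mmol/L is V_std / (c_IS * V_IS).
#'
#' @param model a [measurement_model()].
#' @return Slope, ratio units per mmol/L.
#' @export
nominal_slope <- function(model) {
  stopifnot(inherits(model, "measurement_model"))
  model$sample_volume / (model$is_concentration * model$is_volume)
}

#' Internal-standard monomer amount per prepared sample, nmol
#' @param model a [measurement_model()].
#' @return Amount of labelled monomer added per sample, nmol.
#' @export
is_amount <- function(model) {
  stopifnot(inherits(model, "measurement_model"))
  model$is_concentration * model$is_volume
}
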