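# IDMS core: natural-abundance interference correction, 12C/13C ratios,
# heteroscedastic weighted calibration, inverse prediction, LOD, and
# estimation of the internal-standard concentration.

#' Correct the labelled channel for natural-abundance interference
#'
#' The unlabelled analyte contributes a small fraction `f_nat` of its own
#' peak area to the labelled (13C) channel through natural isotope
#' abundance. The corrected labelled area is
#' `area_13C - f_nat * area_12C`; the unlabelled area is unchanged. A
#' negative corrected area is a hard error (it indicates a mis-set `f_nat`
#' or a missing internal standard), never silently clipped.
#'
#' @param areas data.frame with columns `sample_id`, `area_12C`, `area_13C`.
#' @param f_nat interference fraction, in `[0, 1)`; default 0.044\%.
#' @return The input with an added `corrected_area_13C` column.
#' @examples
#' correct_natural_abundance(
#'   data.frame(sample_id = "a", area_12C = 1e5, area_13C = 5e3))
#' @export
correct_natural_abundance <- function(areas, f_nat = 4.4e-4) {
  if (f_nat < 0 || f_nat >= 1) {
    stop("correct_natural_abundance: f_nat must be in [0, 1)")
  }
  req <- c("area_12C", "area_13C")
  if (!all(req %in% names(areas))) {
    stop("correct_natural_abundance: need columns area_12C and area_13C")
  }
  if (any(areas$area_12C < 0) || any(areas$area_13C < 0)) {
    stop("correct_natural_abundance: areas must be non-negative")
  }
  corrected <- areas$area_13C - f_nat * areas$area_12C
  if (any(corrected < 0)) {
    bad <- if ("sample_id" %in% names(areas)) {
      paste(areas$sample_id[corrected < 0], collapse = ", ")
    } else {
      paste(which(corrected < 0), collapse = ", ")
    }
    stop("correct_natural_abundance: corrected 13C area negative for: ", bad,
         " (check f_nat and that the internal standard was added)")
  }
  areas$corrected_area_13C <- corrected
  areas
}

#' Compute the 12C/13C peak-area ratio
#'
#' Ratio of the unlabelled area to the interference-corrected labelled
#' area, the IDMS measurand that calibration is built on.
#'
#' @param corrected output of [correct_natural_abundance()].
#' @return The input with an added `ratio` column.
#' @export
compute_ratio <- function(corrected) {
  if (!"corrected_area_13C" %in% names(corrected)) {
    stop("compute_ratio: apply correct_natural_abundance() first")
  }
  if (any(corrected$corrected_area_13C <= 0)) {
    stop("compute_ratio: zero corrected 13C area (no internal standard detected)")
  }
  corrected$ratio <- corrected$area_12C / corrected$corrected_area_13C
  corrected
}

#' Ratio-scale measurement SD under the heteroscedastic error model
#'
#' The error model combines an absolute and a relative component in
#' quadrature, in concentration units, and the calibration slope maps it to
#' ratio units:
#' \deqn{\sigma_R(c) = b_1 \sqrt{\sigma_{abs}^2 + (\sigma_{rel} c)^2}}
#'
#' @param concentration concentration(s), mmol/L, non-negative.
#' @param model a `calibration_model` (from [fit_calibration()]).
#' @return SD of the measured ratio at each concentration, ratio units.
#' @export
error_model_sigma <- function(concentration, model) {
  stopifnot(inherits(model, "calibration_model"))
  if (any(concentration < 0)) {
    stop("error_model_sigma: concentration must be non-negative")
  }
  em <- model$error_model
  model$slope * sqrt(em[["sigma_abs"]]^2 + (em[["sigma_rel"]] * concentration)^2)
}

#' Fit the weighted linear calibration of ratio on concentration
#'
#' Weighted least squares of the measured ratio on the standard
#' concentration with weights `1 / sigma_R(c)^2` from the heteroscedastic
#' error model. Because the ratio-scale sigma needs the slope, the fit is
#' iterated once: an unweighted fit supplies the slope inside the weight
#' map, then the weighted fit is final. The intercept absorbs the residual
#' unlabelled signal of the internal standard. The parameter covariance is
#' the known-sigma (unscaled) form `(X' W X)^-1`, so it reflects the stated
#' error model rather than the residual scatter of one particular run; the
#' realized dispersion (reduced chi-square) is reported alongside.
#'
#' @param standards data.frame with columns `true_concentration` (or
#'   `concentration`) and `ratio` (or `observed_ratio`).
#' @param error_model named vector with `sigma_abs` (mmol/L) and
#'   `sigma_rel`; both zero is an error since weights would be undefined.
#' @return A `calibration_model`: `slope`, `intercept`,
#'   `parameter_covariance` (2x2, intercept first), `error_model`,
#'   `n_points`, `concentration_range`, `dispersion`.
#' @export
fit_calibration <- function(standards,
                            error_model = c(sigma_abs = 0.0053,
                                            sigma_rel = 3e-5)) {
  conc <- standards[["true_concentration"]]
  if (is.null(conc)) conc <- standards[["concentration"]]
  ratio <- standards[["ratio"]]
  if (is.null(ratio)) ratio <- standards[["observed_ratio"]]
  if (is.null(conc) || is.null(ratio)) {
    stop("fit_calibration: need concentration and ratio columns")
  }
  if (any(!is.finite(conc)) || any(!is.finite(ratio))) {
    stop("fit_calibration: non-finite concentrations or ratios")
  }
  if (length(unique(conc)) < 3) {
    stop("fit_calibration: need at least 3 distinct concentration levels")
  }
  sa <- error_model[["sigma_abs"]]
  sr <- error_model[["sigma_rel"]]
  if (sa < 0 || sr < 0) stop("fit_calibration: sigmas must be non-negative")
  if (sa == 0 && sr == 0) {
    stop("fit_calibration: error model with both sigmas zero gives undefined weights")
  }

  fit0 <- stats::lm(ratio ~ conc)
  slope0 <- unname(stats::coef(fit0)[2])
  if (slope0 <= 0) stop("fit_calibration: non-positive preliminary slope")
  sigma_r <- slope0 * sqrt(sa^2 + (sr * conc)^2)
  w <- 1 / sigma_r^2
  fit <- stats::lm(ratio ~ conc, weights = w)
  coefs <- stats::coef(fit)
  slope <- unname(coefs[2])
  intercept <- unname(coefs[1])
  if (slope <= 0) stop("fit_calibration: non-positive slope")

  x <- cbind(1, conc)
  xtwx <- crossprod(x * sqrt(w))
  covariance <- solve(xtwx)
  dimnames(covariance) <- list(c("intercept", "slope"),
                               c("intercept", "slope"))
  resid <- ratio - intercept - slope * conc
  dispersion <- sum(w * resid^2) / (length(conc) - 2)

  structure(list(
    slope = slope,
    intercept = intercept,
    parameter_covariance = covariance,
    error_model = c(sigma_abs = sa, sigma_rel = sr),
    n_points = length(conc),
    concentration_range = range(conc),
    dispersion = dispersion
  ), class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("IDMS ratio calibration\n")
  cat(sprintf("  slope     %.6g ratio per mmol/L (SE %.3g)\n", x$slope,
              sqrt(x$parameter_covariance["slope", "slope"])))
  cat(sprintf("  intercept %.6g ratio units (SE %.3g)\n", x$intercept,
              sqrt(x$parameter_covariance["intercept", "intercept"])))
  cat(sprintf("  %d points over %.4g-%.4g mmol/L; reduced chi-square %.3g\n",
              x$n_points, x$concentration_range[1], x$concentration_range[2],
              x$dispersion))
  invisible(x)
}

#' Invert the calibration: ratio to concentration with standard error
#'
#' `c = (R - intercept) / slope`, with a first-order (delta-method)
#' standard error combining the ratio measurement noise (from the error
#' model, evaluated at the estimate, unless `ratio_sd` is supplied) and the
#' calibration parameter covariance. Ratios below the intercept give a
#' negative estimate flagged `below_calibration`.
#'
#' @param ratio measured ratio(s), dimensionless.
#' @param model a `calibration_model`.
#' @param ratio_sd optional SD(s) of the measured ratio; recycled.
#' @return data.frame with `concentration` (mmol/L), `se`, `flag`.
#' @export
invert_calibration <- function(ratio, model, ratio_sd = NULL) {
  stopifnot(inherits(model, "calibration_model"))
  if (any(!is.finite(ratio))) stop("invert_calibration: non-finite ratio")
  if (model$slope <= 0) stop("invert_calibration: non-positive slope")
  conc <- (ratio - model$intercept) / model$slope
  if (is.null(ratio_sd)) {
    ratio_sd <- error_model_sigma(pmax(conc, 0), model)
  }
  v <- model$parameter_covariance
  var_c <- (ratio_sd^2 + v[1, 1] + 2 * conc * v[1, 2] + conc^2 * v[2, 2]) /
    model$slope^2
  data.frame(
    concentration = conc,
    se = sqrt(pmax(var_c, 0)),
    flag = ifelse(conc < 0, "below_calibration", NA_character_),
    row.names = NULL
  )
}

#' Limit of detection from the calibration line
#'
#' `LOD = k * SE(intercept) / slope`, the blank-noise convention with
#' multiplier `k` (3.3 by default).
#'
#' @param model a `calibration_model`.
#' @param k multiplier.
#' @return LOD in mmol/L.
#' @export
lod <- function(model, k = 3.3) {
  stopifnot(inherits(model, "calibration_model"))
  se_b0 <- sqrt(model$parameter_covariance["intercept", "intercept"])
  if (!is.finite(se_b0)) stop("lod: degenerate parameter covariance")
  k * se_b0 / model$slope
}

#' Area-response line of the unlabelled channel
#'
#' Ordinary least squares of the raw 12C peak area on the standard
#' concentration. Its slope (counts per mmol/L at the standard prep volume)
#' converts an area to a prep-equivalent concentration, which is what
#' quantifying the labelled IS against the unlabelled calibration requires.
#'
#' @param standards data.frame with `true_concentration` (or
#'   `concentration`) and `area_12C`.
#' @return List with `slope_area`, `intercept_area`, `n_points`.
#' @export
fit_area_response <- function(standards) {
  conc <- standards[["true_concentration"]]
  if (is.null(conc)) conc <- standards[["concentration"]]
  if (is.null(conc) || is.null(standards[["area_12C"]])) {
    stop("fit_area_response: need concentration and area_12C columns")
  }
  if (length(unique(conc)) < 2) {
    stop("fit_area_response: need at least 2 distinct levels")
  }
  fit <- stats::lm(standards[["area_12C"]] ~ conc)
  list(slope_area = unname(stats::coef(fit)[2]),
       intercept_area = unname(stats::coef(fit)[1]),
       n_points = length(conc))
}

#' Estimate the IS suspension concentration from IS-alone runs
#'
#' Runs of the internal standard alone give the labelled peak area; under
#' the equal-molar-response assumption the unlabelled area-response slope
#' converts it to a prep-equivalent concentration, and volume bookkeeping
#' rescales to the suspension:
#' `c_IS = corrected_area_13C / slope_area * V_std / V_IS`.
#'
#' @param is_measurements data.frame with `area_12C`, `area_13C` of runs of
#'   the IS alone.
#' @param area_response result of [fit_area_response()].
#' @param prep a [sample_prep()] giving the standard volume (`broth_volume`)
#'   and IS volume.
#' @param f_nat natural-abundance interference fraction.
#' @return Mean estimated IS concentration, mmol/L.
#' @export
estimate_is_concentration <- function(is_measurements, area_response,
                                      prep = sample_prep(), f_nat = 4.4e-4) {
  stopifnot(inherits(prep, "sample_prep"))
  if (is.null(prep$is_volume) || prep$is_volume <= 0) {
    stop("estimate_is_concentration: missing or non-positive IS volume")
  }
  corrected <- correct_natural_abundance(is_measurements, f_nat = f_nat)
  if (any(corrected$corrected_area_13C <= 0)) {
    stop("estimate_is_concentration: zero 13C area in IS run")
  }
  c_eq <- corrected$corrected_area_13C / area_response$slope_area
  mean(c_eq) * prep$broth_volume / prep$is_volume
}

#' IS concentration implied by the ratio-calibration slope
#'
#' The slope of the ratio calibration is `V_std / (c_IS * V_IS)`, so the
#' IS concentration can be read back from it directly:
#' `c_IS = V_std / (slope * V_IS)`. Useful as a cross-check of
#' [estimate_is_concentration()].
#'
#' @param model a `calibration_model`.
#' @param prep a [sample_prep()].
#' @return IS concentration, mmol/L.
#' @export
is_concentration_from_slope <- function(model, prep = sample_prep()) {
  stopifnot(inherits(model, "calibration_model"),
            inherits(prep, "sample_prep"))
  prep$broth_volume / (model$slope * prep$is_volume)
}
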