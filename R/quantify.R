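# Unit conversions from calibrated prep-equivalent concentrations to broth
# monomer concentration and percent PHB per gram cell dry weight.

#' Cell dry weight from filter weights
#'
#' `(post - pre) / filtered_volume`, with the weight difference in grams and
#' the filtered broth volume in millilitres, giving g/L.
#'
#' @param pre_weight,post_weight filter weight before/after filtration and
#'   drying, g.
#' @param filtered_volume broth volume filtered, mL.
#' @return CDW in g/L.
#' @examples
#' cdw_from_filters(0.1000, 0.1060, 5)  # 1.2 g/L
#' @export
cdw_from_filters <- function(pre_weight, post_weight, filtered_volume = 5) {
  if (any(filtered_volume <= 0)) {
    stop("cdw_from_filters: filtered_volume must be positive")
  }
  if (any(post_weight < pre_weight)) {
    stop("cdw_from_filters: post-weight below pre-weight")
  }
  (post_weight - pre_weight) / filtered_volume * 1000
}

#' Rescale a prep-equivalent concentration to the broth
#'
#' The calibration is expressed in concentrations at the standard prep
#' volume; if a sample was prepared at a different broth volume (e.g. a
#' dilution-series member), conservation of amount rescales:
#' `c_broth = c_prep * V_standard / V_sample`. Identity when the two preps
#' match.
#'
#' @param prep_equivalent_concentration concentration on the calibration
#'   scale, mmol/L.
#' @param prep the sample's [sample_prep()].
#' @param standard_prep the prep the calibration standards used.
#' @return Broth concentration, mmol/L.
#' @export
broth_concentration <- function(prep_equivalent_concentration,
                                prep = sample_prep(),
                                standard_prep = sample_prep()) {
  stopifnot(inherits(prep, "sample_prep"),
            inherits(standard_prep, "sample_prep"))
  if (prep$broth_volume <= 0) {
    stop("broth_concentration: zero broth volume")
  }
  prep_equivalent_concentration * standard_prep$broth_volume / prep$broth_volume
}

#' Percent PHB per gram cell dry weight
#'
#' `content = c_broth * M_monomer / 1000 / CDW * 100`, i.e. the monomer
#' mass concentration in g/L divided by the biomass concentration.
#'
#' @param broth_conc broth monomer concentration, mmol/L.
#' @param cdw cell dry weight, g/L, positive.
#' @param monomer_mass monomer unit molar mass, g/mol.
#' @return PHB content, \% g per g CDW.
#' @examples
#' phb_content(2.79, 1.2)  # about 20 %
#' @export
phb_content <- function(broth_conc, cdw, monomer_mass = 86.09) {
  if (any(cdw <= 0)) stop("phb_content: cdw must be positive")
  broth_conc * monomer_mass / 1000 / cdw * 100
}

#' Broth concentration implied by a PHB content (inverse of [phb_content()])
#'
#' @param content PHB content, \% g per g CDW.
#' @param cdw cell dry weight, g/L.
#' @param monomer_mass monomer unit molar mass, g/mol.
#' @return Broth monomer concentration, mmol/L.
#' @export
concentration_from_content <- function(content, cdw, monomer_mass = 86.09) {
  if (any(cdw <= 0)) stop("concentration_from_content: cdw must be positive")
  content / 100 * cdw / monomer_mass * 1000
}

#' Quantify samples end to end from raw channel areas
#'
#' Applies the natural-abundance correction, computes ratios, inverts the
#' calibration, rescales to broth concentration, and converts to percent
#' PHB per CDW. This is the per-sample quantification path the analysis
#' drivers and the validation battery run on.
#'
#' @param areas data.frame with `sample_id`, `area_12C`, `area_13C` (extra
#'   columns are carried through).
#' @param calibration a `calibration_model`.
#' @param cdw cell dry weight, g/L (scalar or per-row).
#' @param prep,standard_prep sample and calibration-standard preps.
#' @param f_nat natural-abundance interference fraction.
#' @param monomer_mass monomer molar mass, g/mol.
#' @return The input plus `ratio`, `concentration_mmol_L` (prep scale),
#'   `se_mmol_L`, `broth_mmol_L`, `cdw_g_L`, `phb_content_pct`, `flag`.
#' @export
quantify_samples <- function(areas, calibration, cdw,
                             prep = sample_prep(),
                             standard_prep = sample_prep(),
                             f_nat = 4.4e-4, monomer_mass = 86.09) {
  stopifnot(inherits(calibration, "calibration_model"))
  out <- compute_ratio(correct_natural_abundance(areas, f_nat = f_nat))
  inv <- invert_calibration(out$ratio, calibration)
  out$concentration_mmol_L <- inv$concentration
  out$se_mmol_L <- inv$se
  out$broth_mmol_L <- broth_concentration(inv$concentration, prep, standard_prep)
  out$cdw_g_L <- cdw
  out$phb_content_pct <- phb_content(out$broth_mmol_L, cdw, monomer_mass)
  out$flag <- inv$flag
  over <- !is.na(out$phb_content_pct) & out$phb_content_pct > 100
  out$flag[over] <- "content_above_100"
  out
}
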