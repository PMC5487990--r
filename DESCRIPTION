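Package: phbidms
Title: Isotope Dilution GC-MS Quantification of Poly(3-Hydroxybutyrate)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification of the poly(3-hydroxybutyrate) monomer in
    microbial biomass by gas chromatography isotope dilution mass
    spectrometry (GC-IDMS) with a uniformly 13C-labelled cell suspension as
    internal standard. Implements natural-abundance isotope interference
    correction of the labelled channel, 12C/13C peak-area ratios,
    heteroscedastic weighted calibration regression with inverse prediction,
    conversion to percent PHB per gram cell dry weight, and the method's
    validation battery (pooled relative standard deviations, standard
    addition recovery with one-sample t-test, two-method comparison, and a
    dilution-series matrix-effect model comparison). A synthetic-data module
    generates calibration standards, broth samples, spiked pairs, dilution
    series and selected-ion-monitoring chromatograms under the method's
    measurement model, so the whole pipeline is exercised end to end without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
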