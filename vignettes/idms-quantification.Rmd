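---
title: "Quantifying PHB by isotope dilution GC-MS: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying PHB by isotope dilution GC-MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phbidms)
```

## The measurement problem

Poly(3-hydroxybutyrate) (PHB) content in microbial biomass is classically
measured by propanolysis followed by GC with external calibration, which
needs milligrams of biomass and is sensitive to losses in every processing
step. Isotope dilution mass spectrometry (IDMS) sidesteps both problems: a
uniformly ¹³C-labelled cell suspension containing labelled PHB is added to
the broth *before* any processing, so analyte and internal standard (IS)
experience identical losses, derivatization yield and matrix effects. The
measurand is the ratio of the unlabelled to the labelled monomer peak in
two selected-ion-monitoring (SIM) channels, and everything that scales both
channels equally cancels.

`phbidms` implements the computational side of this method end to end, and
— since no raw chromatograms are publicly available for it — pairs the
pipeline with a synthetic-data module that generates inputs under the
method's own measurement model, so every stage can be exercised and tested
against known ground truth.

## The measurement model

All concentrations are mmol/L of the monomer unit (PHB)₁, all volumes µL,
so amounts (concentration × volume) are nmol. With a standard (or broth)
volume $V_s$ and an IS addition of $V_{IS}$ µL at $c_{IS}$ mmol/L, the
noise-free measured ratio at analyte concentration $c$ is

$$R(c) = \frac{c\,V_s}{c_{IS} V_{IS}} + r_0,$$

where $r_0$ is the residual unlabelled signal of the IS suspension (its
cells are not 100 % labelled). The calibration line therefore has slope
$b_1 = V_s/(c_{IS} V_{IS})$ and intercept $b_0 = r_0$: the IS's own ¹²C
contribution is absorbed by the offset and subtracted automatically on
inversion. At the defaults ($V_s = 1000$, $V_{IS} = 200$,
$c_{IS} = 9.3$) the slope is $1/1.86 \approx 0.538$ per mmol/L.

Two cross-channel effects are modelled explicitly:

* **Natural-abundance interference.** The unlabelled analyte contributes a
  fraction $f_{nat}$ (default 0.044 %) of its own area to the ¹³C channel;
  `correct_natural_abundance()` subtracts $f_{nat}\,A_{12}$ from the raw
  ¹³C area before the ratio is formed. A negative corrected area is a hard
  error, never clipped: it means $f_{nat}$ is mis-set or the IS is missing,
  and clipping would hide that.
* **Matrix enhancement.** Co-injected cell matrix enhances the raw response
  of *both* channels by a common multiplicative factor, modelled as linear
  in the matrix load ($1 + \kappa d$ with $d$ the ¹²C/¹³C volume ratio).
  The default $\kappa = 0.4/3.7$ reproduces a 40 % area increase at the top
  of the dilution-series range. Because both channels scale together, the
  ratio — and hence every reported concentration — is invariant; the test
  suite asserts this invariance exactly.

## The heteroscedastic error model and its ordering ambiguity

Ratio noise is described by two parameters combined in quadrature in
concentration units and mapped to ratio units through the slope:

$$\sigma_R(c) = b_1\sqrt{\sigma_{abs}^2 + (\sigma_{rel}\,c)^2}.$$

The fitted pair reported for this method is 0.0053 mmol/L and
3 × 10⁻⁵, but the wording attaches the unit to the wrong member, so the
assignment is genuinely ambiguous. The package defaults to
$\sigma_{abs} = 0.0053$ mmol/L, $\sigma_{rel} = 3\times10^{-5}$, and both
are plain configurable fields of `measurement_model()`.

The two readings are not equivalent in consequence. Under the default
reading the limit of detection computes to ≈ 0.0033 mmol/L, *above* the
lowest calibration level (0.001 mmol/L): the bottom of the claimed
four-orders calibration range would then be unmeasurable, and per-level
back-calculation accuracy there is statistically meaningless (the stage-2
analysis script shows exactly this). Under the swapped reading
($\sigma_{abs} = 3\times10^{-5}$ mmol/L, $\sigma_{rel} = 0.53\,\%$) the
noise is ≈ 3 % of the level at 0.001 mmol/L and ≈ 0.5 % at 11 mmol/L, and
back-calculation is accurate across the whole span. The linearity check in
the acceptance suite therefore uses the swapped configuration — the only
self-consistent one for a four-orders calibration — while every simulation
tied to the published replication and recovery statistics keeps the default
ordering, which is what those statistics were stated with.

## Calibration, inversion, LOD

`fit_calibration()` runs weighted least squares with weights
$1/\sigma_R(c)^2$. Since $\sigma_R$ needs the slope, the fit is iterated
exactly once: an unweighted fit supplies the slope inside the weight map,
then the weighted fit is final. One step is deterministic and sufficient at
these noise levels — the weights depend on the slope only through a common
factor plus the $\sigma_{rel}$ term, so further iterations move the
estimates by far less than their standard errors.

The parameter covariance is the known-sigma form $(X^TWX)^{-1}$ rather than
the residual-rescaled one: the error model is treated as externally given
(as it is in the method), so the LOD and inverse-prediction uncertainties
reflect the stated model, not the scatter of one particular run. The
realized reduced chi-square is reported alongside as a consistency
diagnostic.

Inverse prediction is $\hat c = (R - b_0)/b_1$ with a first-order
(delta-method) standard error combining the ratio noise and the parameter
covariance; ratios below the intercept yield negative estimates flagged
`below_calibration`. The LOD uses the $3.3\,\mathrm{SE}(b_0)/b_1$
convention — the method reports an LOD without a formula, and this is the
standard calibration-line convention. Concentration units only are
reported; the published µg/g-CDW figure depends on an unstated biomass
normalization.

## The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions: calibration 0.001–11 mmol/L (12 log-spaced levels × 3
injections), broth at 1.2 g/L CDW with 20 % (g/g) PHB — i.e.
$0.20 \times 1.2 / 86.09 \times 1000 = 2.79$ mmol/L of monomer — in a
nested design of 2 cultures × 3 processed samples × 3 injections, a paired
spike of 2.3 mmol/L, and a dilution series over volume ratios 0.05–3.7.
The monomer mass 86.09 g/mol is the PHB repeat unit C₄H₆O₂ (results are
molar monomer units, not the free acid); it is configurable.

Noise enters at three levels, chosen to mirror where variance arises
physically:

* processing noise (CV 1.2 % by default where the nested design is
  simulated) multiplies the analyte amount once per processed replicate;
* injection noise (CV 1.5 %) multiplies it once per injection;
* the heteroscedastic error model adds ratio-scale noise to every
  measurement.

Multiplicative noise is applied to the analyte-derived part of the ratio,
$R - r_0$, not to the full ratio: that makes the generated concentration CV
equal the stated CV exactly, which is what the replication statistics refer
to. The two CV defaults are the published analytical (1.5 %) and processing
(so that $\sqrt{1.2^2+1.5^2} \approx 1.9$, the published technical
reproducibility) components.

SIM traces are rendered as single Gaussian peaks sampled at ≥ 20 points per
peak over ±8σ, with optional baseline and white noise. The generator does
*not* emulate derivatization chemistry, retention-time drift, peak tailing,
co-eluting interferences, or detector saturation — so passing tests
demonstrate correctness of the computational pipeline under its stated
measurement model, not robustness to every pathology of real chromatograms.

All randomness flows through one explicit seed per generator call and the
caller's RNG state is restored; there is no hidden global state.

## Peak integration

The vendor integrator used on the real instrument is undocumented; since
the acquisition needed no baseline correction, a baseline-free trapezoidal
quadrature over an explicit window is a faithful and testable replacement.
The default window is apex ± 5σ with σ estimated from the half-height
width; the apex is the global maximum with ties broken by the earliest
time. Windows with fewer than 20 points violate the sampling-density
contract and are flagged (result still returned). The integrator is checked
against a 100×-denser midpoint quadrature and against closed-form Gaussian
areas; at 20 points per peak the discretization error is far below 0.1 %.

## Validation battery: interpretations made explicit

Three published procedures are specified only by name; the package commits
to one reading of each and labels it in its report output:

* **Recovery formula.** Recovery per sample is
  $(R_{spiked} - R_{base}) / (b_1\,c_{spike}) \times 100$. The reference is
  the *intercept-free* calibration ratio of the spike concentration: the
  intercept cancels in the numerator's difference, so dividing by a
  ratio that still contains $r_0$ would bias every recovery low by
  $r_0/(b_1 c_{spike})$. With all noise off the estimator returns exactly
  100 % by construction. The one-sample t-test against µ = 100 % uses
  α = 0.05; the degenerate noise-free case (zero variance) is reported as
  t = 0, p = 1 when recoveries equal 100 exactly.
* **Matrix-effect "chi-test".** Each dilution-series measurement is
  inverted and divided by its volume ratio; absent a matrix effect this
  recalculated base concentration is constant (H0), a matrix effect shows
  as a linear trend (H1). Both are fitted by WLS with weights from the
  error model propagated through the normalization, and
  $\Delta\chi^2 = \chi^2_{H0} - \chi^2_{H1}$ is referred to $\chi^2_1$;
  p > 0.05 rejects H1. Under H0 data the test's type-I error is ≈ 5 %
  (property-tested at 1000 seeds).
* **RSD nesting.** Analytical RSD pools within-sample injection variance
  (variances, not SDs, are pooled — nearly unbiased at triplicates);
  technical RSD pools the per-culture CV across all individual
  measurements of its processed replicates. One structural consequence is
  worth knowing: with only three process draws per culture, the expected
  sample variance across the nine measurements is
  $0.75\,\sigma_{proc}^2 + \sigma_{inj}^2$, so the technical RSD estimator
  sits slightly below the quadrature sum $\sqrt{1.2^2+1.5^2} = 1.92$ —
  around 1.8 % on average — exactly as a real experiment of this size
  would.
* **Method comparison.** Two-sample comparisons use the Welch
  unequal-variance t-test (the safe default when only "t-test" is stated),
  implemented from summary statistics since published comparisons provide
  only mean ± SD and n.

## Estimating the IS concentration

The IS suspension's own concentration must itself be measured. Its labelled
amount cannot be read from the ratio calibration directly (the slope
already contains $c_{IS}$), so `estimate_is_concentration()` quantifies the
corrected ¹³C area of IS-alone runs against the *unlabelled area-response
line* (OLS of ¹²C area on standard concentration), assuming equal molar
response of the two isotopologues, then rescales by
$V_s/V_{IS}$. The algebraically independent shortcut
$c_{IS} = V_s/(b_1 V_{IS})$ (`is_concentration_from_slope()`) serves as a
cross-check; the two routes agree on synthetic data and both recover
9.3 mmol/L.

## Problem sizes and determinism

The simulations behind the test suite and the acceptance analysis use the
study's own design sizes (36-point calibrations, 18-measurement nested
designs, 6 spiked pairs, 18-record dilution series), with seed-averaged
statistics over 100–1000 replicate seeds depending on the estimator's
variance — enough for the Monte-Carlo error of each checked mean to sit
well inside its acceptance band. Every pipeline artifact carries the
package version and a hash of the scientific configuration; rerunning any
stage with the same seed reproduces its output byte for byte.

## Known limitations

* Single cross-channel interference term only; a full mass-isotopomer
  correction matrix is unnecessary for this two-channel design and is not
  provided.
* No copolymer channels (PHV, P4HB); the approach extends but standards
  and ions are not specified here.
* The pellet wash/resuspension step is assumed lossless for the *ratio*
  (both isotopologues are present from the start — that is the point of
  early IS addition); an absolute recovery factor below 1 is invisible to
  this method by design.
* Calibration standards are assumed prepared at the same total prep volume
  as samples, making the volume correction an identity by default;
  `broth_concentration()` handles the general case.
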