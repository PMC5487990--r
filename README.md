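# phbidms

Quantification of poly(3-hydroxybutyrate) (PHB) monomer in microbial
biomass by GC isotope dilution mass spectrometry (GC-IDMS), for analytical
and metabolic-engineering labs that screen PHB-producing strains from
micrograms of biomass. A uniformly ¹³C-labelled cell suspension added to
the broth before any processing serves as internal standard (IS), so
processing losses and matrix effects cancel in the ¹²C/¹³C peak-area
ratio. The package implements the full computational pipeline plus the
method's validation battery, and ships a tested synthetic-data module that
emulates the measurement model, so everything runs end to end without
instrument data.

## The model

With broth/standard volume $V_s$ (µL) and $V_{IS}$ µL of IS at $c_{IS}$
mmol/L, the measured ratio at analyte concentration $c$ (mmol/L monomer
units) is

$$R(c) = \frac{c\,V_s}{c_{IS} V_{IS}} + r_0,$$

so the calibration line's slope is $V_s/(c_{IS}V_{IS})$ and its intercept
absorbs the residual unlabelled signal $r_0$ of the IS. Before the ratio is
formed, the labelled channel is corrected for natural-abundance
interference, $A_{13}^{corr} = A_{13} - f_{nat}A_{12}$ with
$f_{nat} = 0.044\,\%$. Calibration is weighted least squares under the
heteroscedastic error model
$\sigma_R(c) = b_1\sqrt{\sigma_{abs}^2 + (\sigma_{rel}c)^2}$; inverse
prediction $\hat c = (R-b_0)/b_1$ carries a delta-method standard error,
and content follows as
$\%\,\mathrm{PHB} = \hat c_{broth}\,M_{monomer}/1000/\mathrm{CDW}\times100$
with $M = 86.09$ g/mol (the C₄H₆O₂ repeat unit) and CDW the cell dry
weight in g/L.

Validation operations: pooled analytical/technical RSDs over the nested
culture × sample × injection design, standard-addition recovery with a
one-sample t-test against 100 %, a Welch two-method comparison from summary
statistics, and a dilution-series matrix-effect test (Δχ² of constant vs
linear trend in the volume ratio, 1 d.f.).

## Worked example

```r
library(phbidms)
m   <- measurement_model()                       # 9.3 mmol/L IS, 200 uL per 1 mL broth
std <- make_standards(default_calibration_levels(12), 3, m, seed = 1)
cal <- fit_calibration(std)
cal
#> IDMS ratio calibration
#>   slope     0.537481 ratio per mmol/L (SE 0.000152)
#>   intercept 0.010426 ratio units (SE 0.000534)
#>   36 points over 0.001-11 mmol/L; reduced chi-square 0.821
lod(cal)                                          # 0.00328 mmol/L

broth <- make_broth_samples(cdw = 1.2, phb_content = 0.20,
                            process_cv = 0.012, injection_cv = 0.015,
                            model = m, seed = 2)
res <- quantify_samples(broth, cal, cdw = 1.2)
mean(res$phb_content_pct)                         # 20.12 % g/g CDW (truth: 20)
sd(res$phb_content_pct)                           # 0.42

standard_addition_recovery(
  make_recovery_experiment(2.3, 2.3, model = m, seed = 3), cal)
#> Standard-addition recovery: 100.1 +/- 0.4 % (n = 6)
#>   t = 0.515, df = 5, p = 0.629 -> no bias (H0 retained)
```

The slope is the nominal $1/(9.3 \times 0.2) = 0.5376$ within its standard
error; the intercept recovers the generator's IS offset (0.01); the broth
simulated at 20 % PHB content quantifies to 20.1 ± 0.4 %; and spiking
2.3 mmol/L is recovered at 100 % with the null hypothesis of unbiasedness
retained.

## Analysis workflow

Numbered drivers under `analysis/` run the whole study on synthetic data
and write tables under `results/`:

1. `01_simulate.R` — standards, nested broth replicates, spike pairs,
   dilution series, IS-alone runs
2. `02_calibrate.R` — weighted calibration, LOD, per-level
   back-calculation, IS concentration by two independent routes
3. `03_quantify.R` — concentrations and % PHB per g CDW
4. `04_validate.R` — RSDs, recovery t-test, method comparison,
   matrix-effect test, ¹³C area-response table
5. `05_trace_roundtrip.R` — renders every measurement as SIM traces,
   re-integrates, and re-quantifies

Run each with `Rscript analysis/01_simulate.R` (in order) from the
repository root.

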