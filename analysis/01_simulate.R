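#!/usr/bin/env Rscript
# Stage 1: generate every input the quantification pipeline consumes, at the
# method's stated operating conditions -- calibration standards spanning
# 0.001-11 mmol/L against the 9.3 mmol/L labelled-cell-suspension IS, nested
# broth replicates (2 cultures x 3 processed samples x 3 injections at
# 1.2 g/L CDW, 20% PHB), a paired 2.3 mmol/L spike experiment, and a matrix
# dilution series over 12C/13C volume ratios 0.05-3.7.

library(phbidms)

seed <- 1L
dir.create("results", showWarnings = FALSE)
model <- measurement_model()
meta <- c(stage = "simulate", seed = as.character(seed))

standards <- make_standards(default_calibration_levels(12), 3, model,
                            seed = seed + 1L)
write_csv_with_meta(standards, "results/standards.csv", meta)
cat(sprintf("standards: %d injections over %g-%g mmol/L\n",
            nrow(standards), min(standards$true_concentration),
            max(standards$true_concentration)))

broth <- do.call(rbind, lapply(1:2, function(k) {
  make_broth_samples(1.2, 0.20, 3, 3, process_cv = 0.012,
                     injection_cv = 0.015, model = model,
                     seed = seed + 10L + k, culture = sprintf("culture%d", k))
}))
write_csv_with_meta(broth, "results/samples.csv", meta)
cat(sprintf("broth: %d measurements, true concentration %.3f mmol/L (20%% of 1.2 g/L)\n",
            nrow(broth), broth$true_broth_concentration[1]))

recovery <- make_recovery_experiment(2.3, 2.3, n_cultures = 2, n_samples = 3,
                                     model = model, seed = seed + 20L)
write_csv_with_meta(recovery, "results/recovery_pairs.csv", meta)
cat(sprintf("spike experiment: %d base/spiked pairs at +2.3 mmol/L\n",
            nrow(recovery)))

dilution <- make_dilution_series(c(0.05, 0.2, 0.5, 1, 2, 3.7),
                                 base_concentration =
                                   broth$true_broth_concentration[1],
                                 n_replicates = 3, model = model,
                                 seed = seed + 30L)
write_csv_with_meta(dilution, "results/dilution_series.csv", meta)
cat(sprintf("dilution series: %d records over volume ratios %.2f-%.1f (max area enhancement %.2fx)\n",
            nrow(dilution), min(dilution$volume_ratio),
            max(dilution$volume_ratio), max(dilution$enhancement)))

is_runs <- make_is_runs(3, model, seed = seed + 40L)
write_csv_with_meta(is_runs, "results/is_runs.csv", meta)
cat("IS-alone runs: 3 injections of the internal standard suspension\n")
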