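#!/usr/bin/env Rscript
# The cross-sequence experiment: a simulated five-subject cohort is acquired
# with the proton-density and T1-weighted gradient-echo presets and the
# spin-echo preset (multi-peak fat model), the gradient-echo data are
# additionally reformatted to the 0.8 x 0.8 x 7 mm grid, and all five
# datasets are quantified under shared, registered segmentation masks.
# Expected findings: low resolution tracks high resolution; the T1-weighted
# gradient echo runs a little high; the spin echo runs far higher, and
# increasingly so in low-density breasts (the multi-peak fat leak that the
# one-peak separation misassigns to water).
# Writes results/comparison_results.csv and a JSON report.

library(dixonfgt)
dir.create("results", showWarnings = FALSE)

cfg <- default_run_config(n_subjects = 5L, noise_sd = 0.02,
                          rng_seed = 20160324L, output_dir = "results/comparison")
report <- run_experiment(cfg, "comparison")

cat("\nPer-dataset cohort summary (%FGT):\n")
print(report$report$summary[, c("dataset", "pct_fgt_mean", "pct_fgt_sd",
                                "pct_fgt_range", "c_mean")], row.names = FALSE)
cat("\nAgainst the high-resolution proton-density reference:\n")
print(report$report$vs_reference, row.names = FALSE)
cat(sprintf("\nrepeated-measures ANOVA across datasets: F = %.1f, p = %.3g\n",
            report$report$anova$F, report$report$anova$p))
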