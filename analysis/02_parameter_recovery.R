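#!/usr/bin/env Rscript
# Does the proton-density Dixon pipeline recover known %FGT? Noise-free
# phantoms spanning 10-90% true fibroglandular fraction are pushed through
# simulation -> separation -> segmentation -> calibration -> quantification,
# with the idealised single-peak fat model so that separation arithmetic is
# exact. Expected finding: recovery within a fraction of a percentage point
# at every density. Writes results/parameter_recovery.csv.

library(dixonfgt)
dir.create("results", showWarnings = FALSE)

tissues <- tissue_properties(fat_spectrum = fat_spectrum_single_peak())
rows <- list()
for (f in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  ph <- generate_phantom(phantom_spec(composition = list(type = "blobs",
                                                         fraction = f,
                                                         scale_mm = 8),
                                      noise_sd = 0, rng_seed = 400 + round(100 * f)))
  got <- acquire_and_quantify(ph, "hr_gre_pd", tissues = tissues)$results
  got$true_pct_fgt <- ph$true_fgt_percent[got$laterality]
  got$error_pct <- got$pct_fgt - got$true_pct_fgt
  rows[[length(rows) + 1L]] <- got
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/parameter_recovery.csv", row.names = FALSE)
print(tab[, c("laterality", "true_pct_fgt", "pct_fgt", "error_pct", "c")],
      row.names = FALSE)
cat(sprintf("\nmax |error| = %.3f %%FGT points across %d breasts\n",
            max(abs(tab$error_pct)), nrow(tab)))
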