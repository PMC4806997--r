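#' Published reference statistics for the six Dixon datasets
#'
#' Summary statistics reported by a ten-volunteer two-point Dixon breast
#' density study at 1.5 T, on which the simulator's presets are modelled:
#' per-dataset cohort means and sample standard deviations of FGT volume
#' (cm^3), total breast volume (cm^3), %FGT and the signal-intensity
#' correction factor (`reference_cohort_summary`); Bland-Altman
#' coefficients of repeatability and variation between the repeat
#' proton-density exams (`reference_agreement`); and the reported
#' between-dataset mean %FGT differences and Pearson correlations
#' (`reference_comparisons`). Only these printed summaries are shipped; the
#' underlying per-volunteer measurements were distributed as a separate
#' supplementary file and are not included.
#'
#' Dataset codes: `hr_gre_pd` (reference high-resolution proton-density
#' gradient echo), `hr_gre_pd_r` (its repeat exam), `hr_gre_t1`, `lr_gre_pd`
#' and `lr_gre_t1` (reformatted low-resolution versions), `lr_se_t1`
#' (native low-resolution spin echo).
#'
#' @return a data.frame.
#' @export
reference_cohort_summary <- function() {
  utils::read.csv(system.file("extdata", "cohort_reference_summary.csv",
                              package = "dixonfgt"), stringsAsFactors = FALSE)
}

#' @rdname reference_cohort_summary
#' @export
reference_agreement <- function() {
  utils::read.csv(system.file("extdata", "reference_agreement.csv",
                              package = "dixonfgt"), stringsAsFactors = FALSE)
}

#' @rdname reference_cohort_summary
#' @export
reference_comparisons <- function() {
  utils::read.csv(system.file("extdata", "reference_comparisons.csv",
                              package = "dixonfgt"), stringsAsFactors = FALSE)
}

#' Implied coefficient of repeatability from a reported CoV
#'
#' Internal-consistency check linking the two Bland-Altman summaries: with
#' `CoV = sd_d / (sqrt(2) xbar) * 100`, the coefficient of repeatability
#' `1.96 sd_d` is recoverable from a reported CoV and the mean of the two
#' exam means as `1.96 * (CoV / 100) * sqrt(2) * xbar`.
#'
#' @param cov_percent reported coefficient of variation, percent.
#' @param mean_1,mean_2 the two exam means of the measure.
#' @return the implied coefficient of repeatability, in the measure's units.
#' @export
implied_cor_from_cov <- function(cov_percent, mean_1, mean_2) {
  xbar <- (mean_1 + mean_2) / 2
  1.96 * (cov_percent / 100) * sqrt(2) * xbar
}
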