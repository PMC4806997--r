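#' Bland-Altman agreement statistics
#'
#' For paired test-retest measures, computes the mean difference
#' (`value_1 - value_2`), the sample standard deviation of the differences
#' (n - 1 denominator), the 95% limits of agreement
#' `mean_difference +/- 1.96 sd`, the coefficient of repeatability
#' `CoR = 1.96 sd`, and the coefficient of variation
#' `CoV = sd / (sqrt(2) xbar) * 100` where `xbar` is the mean of the
#' per-pair means. The sqrt(2) converts the standard deviation of a
#' difference of two equal-variance measurements to the within-subject
#' standard deviation of a single measurement.
#'
#' @param pairs data.frame (or list) with columns/elements `value_1`,
#'   `value_2`, or a 2-column matrix.
#' @param measure optional measure name carried into the result.
#' @return an `AgreementStats` list: `n`, `mean_difference`,
#'   `sd_differences`, `loa_lower`, `loa_upper`, `cor`, `cov_percent`,
#'   `mean_of_means`, `measure`.
#' @export
bland_altman <- function(pairs, measure = NA_character_) {
  if (is.matrix(pairs)) pairs <- data.frame(value_1 = pairs[, 1], value_2 = pairs[, 2])
  v1 <- pairs$value_1; v2 <- pairs$value_2
  if (length(v1) < 2L) stop("Bland-Altman needs at least 2 pairs")
  if (any(!is.finite(v1)) || any(!is.finite(v2))) stop("non-finite values in pairs")
  d <- v1 - v2
  md <- mean(d)
  sd_d <- stats::sd(d)
  xbar <- mean((v1 + v2) / 2)
  cov_pct <- if (xbar == 0) {
    if (sd_d == 0) 0 else stop("coefficient of variation undefined: mean of means is 0")
  } else sd_d / (sqrt(2) * xbar) * 100
  structure(list(n = length(d), mean_difference = md, sd_differences = sd_d,
                 loa_lower = md - 1.96 * sd_d, loa_upper = md + 1.96 * sd_d,
                 cor = 1.96 * sd_d, cov_percent = cov_pct,
                 mean_of_means = xbar, measure = measure),
            class = "AgreementStats")
}

#' @export
print.AgreementStats <- function(x, ...) {
  cat("<AgreementStats>", if (!is.na(x$measure)) x$measure, " n =", x$n, "\n",
      " mean difference:", signif(x$mean_difference, 4),
      " sd:", signif(x$sd_differences, 4), "\n",
      " limits of agreement: [", signif(x$loa_lower, 4), ",",
      signif(x$loa_upper, 4), "]\n",
      " CoR: +/-", signif(x$cor, 4), "  CoV:", signif(x$cov_percent, 3), "%\n")
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' @param xs,ys numeric vectors, length >= 3, each with non-zero variance.
#' @return scalar correlation coefficient.
#' @export
pearson_r <- function(xs, ys) {
  if (length(xs) != length(ys)) stop("xs and ys must have equal length")
  if (length(xs) < 3L) stop("Pearson correlation needs at least 3 observations")
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0)
    stop("Pearson correlation undefined for a zero-variance input")
  stats::cor(xs, ys, method = "pearson")
}

#' Paired two-sided Student's t-test
#'
#' @param pairs data.frame with `value_1`, `value_2`, or a 2-column matrix.
#' @return list with `t`, `p`, `df`, `mean_difference`.
#' @export
paired_t <- function(pairs) {
  if (is.matrix(pairs)) pairs <- data.frame(value_1 = pairs[, 1], value_2 = pairs[, 2])
  d <- pairs$value_1 - pairs$value_2
  if (length(d) < 2L) stop("paired t-test needs at least 2 pairs")
  if (stats::sd(d) == 0)
    stop("paired t-test undefined: the differences have zero variance")
  ht <- stats::t.test(pairs$value_1, pairs$value_2, paired = TRUE,
                      alternative = "two.sided")
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter),
       mean_difference = unname(ht$estimate))
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject factor = dataset, subject = breast. Fitted with
#' `aov(value ~ dataset + Error(breast))`; the dataset effect is tested
#' against the within-breast residual.
#'
#' @param mat numeric matrix, breasts (rows) x datasets (columns), complete.
#' @return list with `F`, `p`, `df1`, `df2`.
#' @export
rm_anova <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L || ncol(mat) < 2L)
    stop("repeated-measures ANOVA needs >= 2 breasts and >= 2 datasets")
  if (any(!is.finite(mat))) stop("matrix has missing cells")
  df <- data.frame(value = as.vector(mat),
                   breast = factor(rep(seq_len(nrow(mat)), ncol(mat))),
                   dataset = factor(rep(seq_len(ncol(mat)), each = nrow(mat))))
  fit <- stats::aov(value ~ dataset + Error(breast), data = df)
  tab <- summary(fit)[["Error: Within"]][[1]]
  df1 <- unname(tab["dataset", "Df"]); df2 <- unname(tab["Residuals", "Df"])
  if (tab["dataset", "Sum Sq"] < .Machine$double.eps * sum(mat^2)) {
    # no between-dataset variation at all: report a null effect rather
    # than the indeterminate 0/0 ratio
    return(list(F = 0, p = 1, df1 = df1, df2 = df2))
  }
  list(F = unname(tab["dataset", "F value"]),
       p = unname(tab["dataset", "Pr(>F)"]), df1 = df1, df2 = df2)
}

#' Cohort comparison report
#'
#' Summarises a per-breast, per-dataset results table the way a
#' cross-sequence %FGT study reports it: per-dataset mean, sample SD and
#' range of each measure; for each dataset, the comparison against a
#' reference dataset (mean %FGT difference, paired t, Pearson r on
#' matched breasts); a left-vs-right paired t-test per dataset; and a
#' one-way repeated-measures ANOVA of %FGT across datasets. No
#' multiple-comparison correction is applied.
#'
#' @param results data.frame with columns `subject`, `laterality`,
#'   `dataset`, `fgt_cm3`, `total_cm3`, `pct_fgt` (and optionally `c`).
#' @param reference dataset name used as the comparison reference.
#' @return a `ComparisonReport` list with elements `summary` (per-dataset
#'   data.frame), `vs_reference` (data.frame), `left_vs_right` (data.frame),
#'   `anova` (list), `reference`.
#' @export
cohort_compare <- function(results, reference = "hr_gre_pd") {
  needed <- c("subject", "laterality", "dataset", "fgt_cm3", "total_cm3", "pct_fgt")
  missing_cols <- setdiff(needed, names(results))
  if (length(missing_cols))
    stop("results table lacks columns: ", paste(missing_cols, collapse = ", "))
  datasets <- unique(results$dataset)
  if (!reference %in% datasets)
    stop("reference dataset '", reference, "' not present in the results table")

  measures <- intersect(c("fgt_cm3", "total_cm3", "pct_fgt", "c"), names(results))
  summ <- do.call(rbind, lapply(datasets, function(ds) {
    sub <- results[results$dataset == ds, ]
    row <- data.frame(dataset = ds, n = nrow(sub))
    for (mname in measures) {
      row[[paste0(mname, "_mean")]] <- mean(sub[[mname]])
      row[[paste0(mname, "_sd")]] <- stats::sd(sub[[mname]])
    }
    row$pct_fgt_range <- diff(range(sub$pct_fgt))
    row
  }))

  key <- function(sub) paste(sub$subject, sub$laterality)
  ref <- results[results$dataset == reference, ]
  ref <- ref[order(key(ref)), ]
  vs <- do.call(rbind, lapply(setdiff(datasets, reference), function(ds) {
    sub <- results[results$dataset == ds, ]
    sub <- sub[order(key(sub)), ]
    if (!identical(key(sub), key(ref)))
      stop("dataset '", ds, "' does not cover the same breasts as the reference")
    tt <- tryCatch(paired_t(data.frame(value_1 = sub$pct_fgt, value_2 = ref$pct_fgt)),
                   error = function(e) list(t = NA_real_, p = NA_real_))
    data.frame(dataset = ds, reference = reference, n = nrow(sub),
               mean_diff_pct_fgt = mean(sub$pct_fgt - ref$pct_fgt),
               t = tt$t, p = tt$p,
               pearson_r = pearson_r(ref$pct_fgt, sub$pct_fgt))
  }))

  lvr <- do.call(rbind, lapply(datasets, function(ds) {
    sub <- results[results$dataset == ds, ]
    l <- sub[sub$laterality == "L", ]; r <- sub[sub$laterality == "R", ]
    l <- l[order(l$subject), ]; r <- r[order(r$subject), ]
    if (nrow(l) != nrow(r) || !identical(l$subject, r$subject))
      return(NULL)
    tt <- tryCatch(paired_t(data.frame(value_1 = l$pct_fgt, value_2 = r$pct_fgt)),
                   error = function(e) list(t = NA_real_, p = NA_real_))
    data.frame(dataset = ds, n_subjects = nrow(l),
               mean_diff_pct_fgt = mean(l$pct_fgt - r$pct_fgt),
               t = tt$t, p = tt$p)
  }))

  wide <- stats::reshape(results[, c("subject", "laterality", "dataset", "pct_fgt")],
                         idvar = c("subject", "laterality"),
                         timevar = "dataset", direction = "wide")
  mat <- as.matrix(wide[, grep("^pct_fgt\\.", names(wide)), drop = FALSE])
  an <- if (ncol(mat) >= 2L && !any(is.na(mat))) rm_anova(mat) else NULL

  structure(list(summary = summ, vs_reference = vs, left_vs_right = lvr,
                 anova = an, reference = reference),
            class = "ComparisonReport")
}

#' Bland-Altman plot
#'
#' Mean-versus-difference scatter with the mean-difference line and the 95%
#' limits of agreement. Requires ggplot2.
#'
#' @param pairs data.frame with `value_1`, `value_2`.
#' @param measure axis label.
#' @return a ggplot object.
#' @export
plot_bland_altman <- function(pairs, measure = "measure") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_bland_altman requires ggplot2")
  ba <- bland_altman(pairs, measure)
  df <- data.frame(m = (pairs$value_1 + pairs$value_2) / 2,
                   d = pairs$value_1 - pairs$value_2)
  ggplot2::ggplot(df, ggplot2::aes(x = m, y = d)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = ba$mean_difference, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = c(ba$loa_lower, ba$loa_upper),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = paste("Mean of paired", measure),
                  y = paste("Difference in", measure)) +
    ggplot2::theme_minimal()
}
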