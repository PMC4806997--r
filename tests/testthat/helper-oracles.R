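# Brute-force statistical oracles, deliberately independent of the package
# implementations: plain loops and textbook formulas only.

oracle_bland_altman <- function(v1, v2) {
  d <- v1 - v2
  n <- length(d)
  md <- sum(d) / n
  sd_d <- sqrt(sum((d - md)^2) / (n - 1))
  xbar <- sum((v1 + v2) / 2) / n
  list(mean_difference = md, sd_differences = sd_d,
       cor = 1.96 * sd_d, cov_percent = sd_d / (sqrt(2) * xbar) * 100)
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

oracle_paired_t <- function(v1, v2) {
  d <- v1 - v2
  n <- length(d)
  md <- sum(d) / n
  sd_d <- sqrt(sum((d - md)^2) / (n - 1))
  tval <- md / (sd_d / sqrt(n))
  list(t = tval, p = 2 * stats::pt(-abs(tval), df = n - 1))
}

# one-way repeated-measures ANOVA by explicit sums of squares
oracle_rm_anova <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  grand <- mean(mat)
  ss_datasets <- n * sum((colMeans(mat) - grand)^2)
  ss_subjects <- k * sum((rowMeans(mat) - grand)^2)
  ss_total <- sum((mat - grand)^2)
  ss_error <- ss_total - ss_datasets - ss_subjects
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  Fv <- (ss_datasets / df1) / (ss_error / df2)
  list(F = Fv, p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}
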