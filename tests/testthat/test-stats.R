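test_that("Bland-Altman handles identical pairs and the worked example", {
  ident <- data.frame(value_1 = c(3, 5, 7), value_2 = c(3, 5, 7))
  ba0 <- bland_altman(ident)
  expect_equal(ba0$mean_difference, 0); expect_equal(ba0$sd_differences, 0)
  expect_equal(ba0$cor, 0); expect_equal(ba0$cov_percent, 0)
  # pairs (1,2), (2,1), (3,3): differences -1, 1, 0
  ba <- bland_altman(data.frame(value_1 = c(1, 2, 3), value_2 = c(2, 1, 3)))
  expect_equal(ba$mean_difference, 0)
  expect_equal(ba$sd_differences, 1)
  expect_equal(ba$cor, 1.96)
  expect_equal(ba$mean_of_means, 2)
  expect_equal(ba$cov_percent, 100 / (sqrt(2) * 2), tolerance = 1e-12)  # 35.36%
  expect_error(bland_altman(data.frame(value_1 = 1, value_2 = 2)), "at least 2")
})

test_that("CoR and CoV behave under pair exchange and rescaling", {
  set.seed(51)
  v1 <- runif(12, 10, 60); v2 <- v1 + rnorm(12)
  a <- bland_altman(data.frame(value_1 = v1, value_2 = v2))
  b <- bland_altman(data.frame(value_1 = v2, value_2 = v1))
  expect_equal(a$cor, b$cor); expect_equal(a$cov_percent, b$cov_percent)
  expect_equal(a$mean_difference, -b$mean_difference)
  k <- 3.7
  s <- bland_altman(data.frame(value_1 = k * v1, value_2 = k * v2))
  expect_equal(s$cov_percent, a$cov_percent, tolerance = 1e-12)
  expect_equal(s$cor, k * a$cor, tolerance = 1e-12)
})

test_that("Pearson correlation endpoints and oracle agreement", {
  x <- c(1, 2, 4, 6, 9)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  y <- c(2.2, 1.9, 4.5, 5.8, 9.3)
  expect_equal(pearson_r(x, y), oracle_pearson(x, y), tolerance = 1e-12)
  expect_error(pearson_r(c(1, 2), c(1, 2)), "at least 3")
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
})

test_that("paired t-test matches its closed form and is antisymmetric", {
  v1 <- c(10, 12, 9, 14, 11); v2 <- c(9, 11.5, 9.4, 12, 10)
  got <- paired_t(data.frame(value_1 = v1, value_2 = v2))
  want <- oracle_paired_t(v1, v2)
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
  swapped <- paired_t(data.frame(value_1 = v2, value_2 = v1))
  expect_equal(swapped$t, -got$t, tolerance = 1e-12)
  expect_equal(swapped$p, got$p, tolerance = 1e-12)
  expect_error(paired_t(data.frame(value_1 = v1, value_2 = v1)), "zero variance")
})

test_that("repeated-measures ANOVA matches the sums-of-squares oracle", {
  set.seed(52)
  mat <- matrix(rnorm(12, 30, 5), nrow = 4, ncol = 3)
  mat[, 2] <- mat[, 2] + 2   # a real dataset effect
  got <- rm_anova(mat)
  want <- oracle_rm_anova(mat)
  expect_equal(got$F, want$F, tolerance = 1e-10)
  expect_equal(got$p, want$p, tolerance = 1e-10)
  expect_equal(got$df1, want$df1); expect_equal(got$df2, want$df2)
  # column permutation leaves F unchanged
  perm <- rm_anova(mat[, c(3, 1, 2)])
  expect_equal(perm$F, got$F, tolerance = 1e-10)
  # identical columns: a null effect, not 0/0
  same <- rm_anova(cbind(mat[, 1], mat[, 1], mat[, 1]))
  expect_equal(same$F, 0); expect_equal(same$p, 1)
  expect_error(rm_anova(matrix(c(1, 2, NA, 4), 2, 2)), "missing")
})

test_that("all statistics match brute force on random small inputs", {
  for (seed in 1:30) {
    set.seed(seed)
    n <- sample(4:12, 1)
    v1 <- runif(n, 5, 80); v2 <- v1 + rnorm(n, 0.5, 2)
    ba <- bland_altman(data.frame(value_1 = v1, value_2 = v2))
    ob <- oracle_bland_altman(v1, v2)
    expect_equal(ba$mean_difference, ob$mean_difference, tolerance = 1e-10)
    expect_equal(ba$cor, ob$cor, tolerance = 1e-10)
    expect_equal(ba$cov_percent, ob$cov_percent, tolerance = 1e-10)
    expect_equal(pearson_r(v1, v2), oracle_pearson(v1, v2), tolerance = 1e-10)
    tt <- paired_t(data.frame(value_1 = v1, value_2 = v2))
    ot <- oracle_paired_t(v1, v2)
    expect_equal(tt$t, ot$t, tolerance = 1e-10)
    mat <- matrix(runif(n * 3, 10, 50), ncol = 3)
    expect_equal(rm_anova(mat)$F, oracle_rm_anova(mat)$F, tolerance = 1e-8)
  }
})

test_that("cohort comparison summarises and compares against the reference", {
  set.seed(53)
  subjects <- paste0("S", 1:6)
  base <- runif(6, 20, 60)
  mk <- function(ds, offset, noise = 0) {
    do.call(rbind, lapply(1:6, function(i) {
      data.frame(subject = subjects[i], laterality = c("L", "R"), dataset = ds,
                 fgt_cm3 = 100, total_cm3 = 300,
                 pct_fgt = base[i] + offset + rnorm(2, 0, noise))
    }))
  }
  # identical datasets: zero mean difference, perfect correlation
  res0 <- rbind(mk("a", 0), mk("b", 0))
  rep0 <- cohort_compare(res0, reference = "a")
  expect_equal(rep0$vs_reference$mean_diff_pct_fgt, 0)
  expect_equal(rep0$vs_reference$pearson_r, 1)
  expect_equal(rep0$anova$F, 0)
  # known offsets are recovered
  res <- rbind(mk("a", 0, 0.3), mk("b", 3, 0.3), mk("c", 12, 0.3))
  rep <- cohort_compare(res, reference = "a")
  expect_equal(rep$vs_reference$mean_diff_pct_fgt[rep$vs_reference$dataset == "b"],
               3, tolerance = 0.5)
  expect_equal(rep$vs_reference$mean_diff_pct_fgt[rep$vs_reference$dataset == "c"],
               12, tolerance = 0.5)
  expect_true(all(rep$vs_reference$pearson_r > 0.99))
  expect_lt(rep$anova$p, 1e-6)
  expect_equal(nrow(rep$summary), 3)
  expect_equal(rep$summary$n, rep(12, 3))
  expect_error(cohort_compare(res, reference = "zz"), "not present")
  expect_error(cohort_compare(res[, -6], reference = "a"), "lacks columns")
})
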