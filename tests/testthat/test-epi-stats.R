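test_that("per-pangene epiallele mean TPM follows the indicator formula", {
  DT <- rbind(c(10, 12, 9, 9, 9), c(1, 2, 3, 4, NA))
  DE <- rbind(c("gbM", "gbM", "UM", "UM", "UM"),
              c("UM", "UM", "teM", NA, "gbM"))
  rownames(DT) <- rownames(DE) <- c("p1", "p2")
  gbm <- mean_tpm_per_epiallele(DT, DE, "gbM")
  um <- mean_tpm_per_epiallele(DT, DE, "UM")
  expect_equal(unname(gbm["p1"]), 11)
  expect_equal(unname(um["p1"]), 9)
  expect_equal(unname(gbm["p1"] - um["p1"]), 2)
  # NA TPM under a defined label does not enter the mean
  expect_true(is.na(gbm["p2"]))
  expect_equal(unname(mean_tpm_per_epiallele(DT, DE, "teM")["p2"]), 3)
  expect_error(mean_tpm_per_epiallele(DT[, 1:3], DE, "UM"), "shape")
})

test_that("indicator means equal the double-loop oracle on random matrices", {
  set.seed(31)
  for (rep in 1:40) {
    n <- sample(3:8, 1); m <- sample(3:8, 1)
    DT <- matrix(round(rlnorm(n * m, 2, 1), 3), n, m)
    DT[runif(n * m) < 0.15] <- NA
    DE <- matrix(sample(c("UM", "gbM", "teM", NA), n * m, TRUE), n, m)
    for (e in c("UM", "gbM", "teM")) {
      expect_equal(unname(mean_tpm_per_epiallele(DT, DE, e)),
                   oracle_mean_tpm(DT, DE, e))
    }
  }
})

test_that("sign test p-values are exact binomial probabilities", {
  r <- paired_difference_tests(rep(1, 10))
  expect_equal(r$sign_test_p, 0.001953125)
  expect_equal(r$n_pos, 10L)
  bal <- paired_difference_tests(c(rep(1, 5), rep(-1, 5)))
  expect_equal(bal$sign_test_p, 1.0)
  # ties drop out of the default test but are reported separately
  tied <- paired_difference_tests(c(rep(1, 10), 0, 0))
  expect_equal(tied$n_tie, 2L)
  expect_equal(tied$sign_test_p, 0.001953125)
  expect_equal(tied$sign_test_p_with_ties,
               stats::binom.test(10, 12, 0.5)$p.value)
  # exact binomial CDF computed by summation as an independent check
  d <- c(rep(1, 8), rep(-1, 3))
  p_manual <- sum(dbinom(c(0:3, 8:11), 11, 0.5))
  expect_equal(paired_difference_tests(d)$sign_test_p, p_manual)
  empty <- paired_difference_tests(numeric(0))
  expect_true(is.na(empty$sign_test_p))
})

test_that("signed-rank test matches wilcox.test with zeros dropped", {
  d <- c(2.5, -1, 3, 4, -0.5, 0, 1.5)
  r <- paired_difference_tests(d)
  expect_equal(r$wilcoxon_p, stats::wilcox.test(d[d != 0])$p.value)
  expect_equal(r$median_d, median(d))
  expect_equal(r$normalized_median_pct, NA_real_)
  expect_equal(paired_difference_tests(d, mean_um = 50)$normalized_median_pct,
               100 * median(d) / 50)
})

test_that("swapping the compared labels negates every difference", {
  set.seed(12)
  DT <- list(t1 = matrix(rlnorm(60, 2, 1), 10, 6))
  DE <- matrix(sample(c("UM", "gbM"), 60, TRUE), 10, 6)
  rownames(DT$t1) <- rownames(DE) <- sprintf("p%d", 1:10)
  fwd <- epiallele_difference_tests(DT, DE, "gbM", "UM")
  rev <- epiallele_difference_tests(DT, DE, "UM", "gbM")
  expect_equal(fwd$median_d, -rev$median_d)
  expect_equal(fwd$n_pos, rev$n_neg)
  expect_equal(fwd$sign_test_p, rev$sign_test_p)
})

test_that("chi-square on duplicate proportions is Pearson without correction", {
  h <- duplicate_proportion_test(c(10, 10), c(10, 10))
  expect_equal(h$statistic, 0)
  expect_equal(h$p_value, 1)
  r <- duplicate_proportion_test(c(50, 10), c(30, 30))
  # hand-computed Pearson statistic: expected 40/20/40/20
  expect_equal(r$statistic, 100 / 40 + 100 / 20 + 100 / 40 + 100 / 20)
  expect_equal(r$df, 1)
  r4 <- duplicate_proportion_test(4 * c(50, 10), 4 * c(30, 30))
  expect_equal(r4$statistic, 4 * r$statistic)
  expect_error(duplicate_proportion_test(c(10, 0), c(10, 0)), "expected")
  expect_error(duplicate_proportion_test(c(10, 10)), "2 x k")
})

test_that("correlation summaries respect range, count and variance rules", {
  meth <- rbind(p1 = c(0.0, 0.3, 0.6), p2 = c(0.1, 0.2, 0.25),
                p3 = c(0.0, 0.4, 0.8), p4 = c(0.0, 0.5, NA))
  tpm <- rbind(p1 = c(1, 2, 3), p2 = c(5, 1, 4), p3 = c(7, 7, 7),
               p4 = c(1, 2, 3))
  r <- methylation_expression_correlation(meth, list(t = tpm))
  expect_equal(unname(r$r["p1", "t"]), 1)          # perfect linearity
  expect_true(is.na(r$r["p2", "t"]))               # range 0.15 < 0.2
  expect_true(is.na(r$r["p3", "t"]))               # TPM standard deviation 0
  expect_true(is.na(r$r["p4", "t"]))               # only 2 usable genomes
  expect_equal(r$summary$n, 1L)
  expect_equal(r$summary$median_r, 1)
  # boundary: a spread of exactly 0.2 qualifies
  m2 <- rbind(p = c(0.1, 0.2, 0.3))
  t2 <- rbind(p = c(3, 1, 2))
  expect_equal(methylation_expression_correlation(m2, list(t = t2))$summary$n, 1L)
})

test_that("correlations recover sign structure on a constructed fixture", {
  set.seed(61)
  n <- 200
  meth <- matrix(runif(n * 8, 0, 0.8), n, 8,
                 dimnames = list(sprintf("p%d", 1:n), NULL))
  up <- matrix(exp(2 * meth + rnorm(n * 8, 0, 0.1)), n, 8,
               dimnames = dimnames(meth))
  down <- matrix(exp(-2 * meth + rnorm(n * 8, 0, 0.1)), n, 8,
                 dimnames = dimnames(meth))
  rs <- methylation_expression_correlation(meth, list(up = up, down = down))
  expect_gt(rs$summary[rs$summary$tissue == "up", ]$median_r, 0.5)
  expect_lt(rs$summary[rs$summary$tissue == "down", ]$median_r, -0.5)
  expect_gt(rs$summary[rs$summary$tissue == "up", ]$pos_neg_ratio, 1)
})
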