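test_that("pearson_with_fit recovers exact linear relations", {
  x <- c(1, 2, 3, 4, 5)
  out <- pearson_with_fit(x, 2 * x + 1)
  expect_equal(out$r, 1)
  expect_equal(out$slope, 2)
  expect_equal(out$intercept, 1)
  out2 <- pearson_with_fit(c(1, 2, 3), c(1, 3, 2))
  expect_equal(out2$r, 0.5)
  expect_error(pearson_with_fit(c(1, 2, 3), c(2, 2, 2)), "zero variance")
  expect_error(pearson_with_fit(1:2, 2:3), "at least 3")
})

test_that("pearson fit is scale-equivariant in x", {
  set.seed(5)
  x <- runif(30); y <- 2 * x + rnorm(30, 0, 0.2)
  base <- pearson_with_fit(x, y)
  for (c in c(0.5, 3, 10)) {
    sc <- pearson_with_fit(c * x, y)
    expect_equal(sc$r, base$r, tolerance = 1e-12)
    expect_equal(sc$slope, base$slope / c, tolerance = 1e-12)
  }
})

test_that("bland_altman reproduces hand-computed limits", {
  out <- bland_altman(c(1, 2, 3), c(2, 2, 2))
  expect_equal(out$mean_diff, 0)
  expect_equal(out$sd_diff, 1)
  expect_equal(out$loa_low, -1.96)
  expect_equal(out$loa_high, 1.96)
  same <- bland_altman(1:5, 1:5)
  expect_equal(same$mean_diff, 0)
  expect_equal(same$sd_diff, 0)
  off <- bland_altman(1:5, 1:5 + 2)
  expect_equal(off$mean_diff, 2)
  expect_equal(off$sd_diff, 0)
  expect_error(bland_altman(1, 2), "at least 2")
})

test_that("limits of agreement span exactly 2 x 1.96 SD", {
  set.seed(8)
  for (i in 1:10) {
    x <- rnorm(20); y <- x + rnorm(20)
    out <- bland_altman(x, y)
    expect_equal(out$loa_high - out$loa_low, 2 * 1.96 * out$sd_diff,
                 tolerance = 1e-12)
  }
})

test_that("ICC is 1 for identity and penalizes constant offsets", {
  x <- c(1, 3, 5, 7, 9)
  expect_equal(icc_agreement(x, x), 1)
  y <- x + 10  # large offset, small spread
  expect_lt(icc_agreement(x, y), pearson_with_fit(x, y)$r)
  expect_error(icc_agreement(1:2, 1:2), "at least 3")
})

test_that("ICC matches an aov mean-squares oracle", {
  x <- c(9, 6, 8, 7, 10, 6)
  y <- c(2, 1, 4, 1, 5, 2)
  expect_equal(icc_agreement(x, y), icc_aov_oracle(x, y), tolerance = 1e-12)
  set.seed(3)
  for (i in 1:10) {
    a <- rnorm(12); b <- a + rnorm(12, 0.5, 0.7)
    expect_equal(icc_agreement(a, b), icc_aov_oracle(a, b),
                 tolerance = 1e-10)
  }
})

test_that("paired t behaves under the null and on degenerate input", {
  # under H0 the p-value is uniform: P(p > 0.05) = 0.95; with 100 seeded
  # replicates a >= 90 count is a 3-sigma-safe check of the null behavior
  set.seed(17)
  hits <- 0
  for (i in 1:100) {
    x <- rnorm(100)
    y <- x + rnorm(100, 0, 0.5)
    if (paired_t(x, y)$p > 0.05) hits <- hits + 1
  }
  expect_gte(hits, 90)
  expect_error(paired_t(c(1, 2, 3), c(3, 4, 5)), "zero-variance")
  a <- c(1, 2, 4); b <- c(2, 4, 5)
  expect_equal(paired_t(a, b)$t, -paired_t(b, a)$t, tolerance = 1e-12)
})

test_that("perfectly separated scores give AUC 1 at full operating point", {
  ivus <- c(10, 12, 9, 0.5, 0.1, 1)
  ccta <- c(5, 6, 7, 0.2, 0.3, 0.1)
  out <- lap_presence_analysis(ivus, ccta, thresholds = 8)
  y <- out[out$rule == "youden", ]
  expect_equal(y$auc, 1)
  expect_equal(y$sensitivity, 100)
  expect_equal(y$specificity, 100)
})

test_that("two-case ROC follows the exhaustive construction", {
  out <- lap_presence_analysis(c(10, 1), c(5, 0), thresholds = 8)
  expect_equal(out$auc[1], 1)
  expect_error(lap_presence_analysis(c(10, 9), c(5, 0), thresholds = 8),
               "threshold 8")
})

test_that("trapezoid AUC equals brute-force Mann-Whitney probability", {
  set.seed(23)
  for (i in 1:25) {
    n <- sample(6:50, 1)
    ivus <- c(runif(n %/% 2, 3, 12), runif(n - n %/% 2, 0, 2.5))
    ccta <- round(runif(n, 0, 10), sample(0:1, 1))  # force score ties
    labels <- ivus >= 3
    if (all(labels) || !any(labels)) next
    out <- lap_presence_analysis(ivus, ccta, thresholds = 3)
    expect_equal(out$auc[1], mann_whitney_auc(labels, ccta),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(41)
  ivus <- runif(80, 0, 12)
  ccta <- 0.6 * ivus + rnorm(80, 0, 2)
  out <- lap_presence_analysis(ivus, ccta, thresholds = 4)
  ref <- suppressMessages(pROC::auc(pROC::roc(ivus >= 4, ccta,
                                              direction = "<")))
  expect_equal(out$auc[1], as.numeric(ref), tolerance = 1e-12)
})

test_that("labels permuted independently of scores give chance AUC", {
  set.seed(29)
  n <- 500
  scores <- runif(n)
  labels_src <- sample(rep(c(TRUE, FALSE), each = n / 2))
  ivus <- ifelse(labels_src, 10, 0)
  out <- lap_presence_analysis(ivus, scores, thresholds = 4)
  expect_gte(out$auc[1], 0.45)
  expect_lte(out$auc[1], 0.55)
})

test_that("agreement_report assembles per-measure statistics", {
  set.seed(55)
  n <- 40
  tpv <- runif(n, 50, 400)
  matched <- tibble::tibble(
    ivus_tpv_mm3 = tpv, ccta_tpv_mm3 = 0.95 * tpv + rnorm(n, 0, 15),
    ivus_cp_mm3 = 0.2 * tpv, ccta_cp_mm3 = 0.19 * tpv + rnorm(n, 0, 4),
    ivus_lap_mm3 = runif(n, 0, 12),
    ccta_lap_mm3 = runif(n, 0, 12))
  rep <- agreement_report(matched, measures = c("tpv", "cp", "lap"))
  expect_s3_class(rep, "agreement_report")
  expect_equal(rep$measures$measure, c("tpv", "cp", "lap"))
  ba <- bland_altman(matched$ivus_tpv_mm3, matched$ccta_tpv_mm3)
  row <- rep$measures[rep$measures$measure == "tpv", ]
  expect_equal(row$mean_diff, ba$mean_diff)
  expect_equal(row$loa_high - row$loa_low, 2 * 1.96 * row$sd_diff)
  expect_true(all(abs(rep$measures$r) <= 1))
  expect_true(all(rep$lap$auc >= 0 & rep$lap$auc <= 1))
  td <- tidy(rep)
  expect_s3_class(td, "tbl_df")
  gl <- glance(rep)
  expect_equal(gl$n_lesions, n)
})
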