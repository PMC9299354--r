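test_that("normality gate keeps normal data and Ln-transforms skewed data", {
  set.seed(101)
  x <- rnorm(200)
  g <- shapiroGate(x)
  expect_identical(g$decision, "normal")
  expect_identical(g$values, x)
  set.seed(102)
  y <- exp(rnorm(200))
  g2 <- shapiroGate(y)
  expect_identical(g2$decision, "ln_transformed")
  expect_gt(shapiro.test(g2$values)$p.value, 0.05)
  expect_error(shapiroGate(rep(1, 10)), class = "degenerateSampleError")
  # skewed data touching zero cannot be Ln-transformed
  set.seed(103)
  z <- c(0, exp(rnorm(100)))
  expect_error(shapiroGate(z), class = "transformInfeasibleError")
})

test_that("group ANOVA matches the pooled t-test identity and detects shifts", {
  # identical groups: no between-group variance
  v <- rep(c(1, 2, 3, 4, 5), 3)
  g <- rep(c("CON", "INP", "TNP"), each = 5)
  a <- groupAnova(v, g)
  expect_equal(a$F, 0, tolerance = 1e-12)
  expect_equal(a$p, 1, tolerance = 1e-12)
  expect_equal(a$eta_squared, 0, tolerance = 1e-12)
  # two groups: F equals the square of the pooled-variance t statistic
  set.seed(111)
  x1 <- rnorm(20); x2 <- rnorm(20, 0.5)
  a2 <- groupAnova(c(x1, x2), rep(c("A", "B"), each = 20))
  tt <- t.test(x1, x2, var.equal = TRUE)
  expect_equal(a2$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(a2$p, tt$p.value, tolerance = 1e-9)
  # power check: unit shift at n = 50, sigma = 1 is detected almost always
  set.seed(112)
  hits <- mean(vapply(1:100, function(i) {
    v3 <- c(rnorm(50, 0), rnorm(50, 0), rnorm(50, 1))
    groupAnova(v3, rep(c("A", "B", "C"), each = 50))$p < 0.05
  }, logical(1)))
  expect_gte(hits, 0.95)
  expect_error(groupAnova(1:5, c("A", "A", "B", "B", "C")),
               class = "insufficientDataError")
})

test_that("Bonferroni-adjusted p values dominate raw ones and cap at 1", {
  set.seed(113)
  a <- groupAnova(rnorm(60), rep(c("A", "B", "C"), each = 20))
  expect_true(all(a$posthoc$p_adj >= a$posthoc$p_raw))
  expect_true(all(a$posthoc$p_adj <= 1))
  expect_equal(a$posthoc$p_adj,
               pmin(1, 3 * a$posthoc$p_raw), tolerance = 1e-12)
})

test_that("rank-based AUC agrees with pair counting, pROC, and the null", {
  # hand-checkable orderings, low scores = cases
  r1 <- rocAnalysis(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE), "low",
                    cutoff = 2.5)
  expect_equal(r1$auc, 1)
  expect_equal(r1$sensitivity, 1)
  expect_equal(r1$one_minus_specificity, 0)
  r2 <- rocAnalysis(c(1, 3, 2, 4), c(TRUE, TRUE, FALSE, FALSE), "low")
  expect_equal(r2$auc, 0.75)
  # perfect separation with a midpoint cutoff
  set.seed(121)
  sep <- rocAnalysis(c(runif(10, 0, 1), runif(10, 2, 3)),
                     rep(c(TRUE, FALSE), each = 10), "low", cutoff = 1.5)
  expect_equal(sep$auc, 1)
  expect_equal(sep$sensitivity, 1)
  expect_equal(sep$one_minus_specificity, 0)
  # label-independent scores sit near 0.5
  set.seed(122)
  nul <- rocAnalysis(rnorm(1000), rep(c(TRUE, FALSE), each = 500), "low")
  expect_lt(abs(nul$auc - 0.5), 0.05)
  # agreement with pROC on tied, noisy data
  set.seed(123)
  sc <- round(c(rnorm(30, 2), rnorm(40, 3)), 1)
  lab <- rep(c(TRUE, FALSE), c(30, 40))
  mine <- rocAnalysis(sc, lab, "low")
  ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, direction = ">",
                                        quiet = TRUE)))
  expect_equal(mine$auc, ref, tolerance = 1e-12)
  expect_error(rocAnalysis(1:5, rep(TRUE, 5)), class = "invalidLabelsError")
})

test_that("Pearson correlation matches the covariance formula", {
  expect_equal(pearsonWithNdi(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearsonWithNdi(1:10, -(1:10))$r, -1)
  x <- c(2, 4, 5, 7, 9)
  y <- c(1, 3, 2, 6, 8)
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearsonWithNdi(x, y)$r, hand, tolerance = 1e-12)
  expect_error(pearsonWithNdi(rep(1, 5), 1:5), class = "degenerateSampleError")
})

test_that("paired bias test flags systematic shifts and tolerates identity", {
  x <- c(10, 12, 14, 16)
  same <- pairedBiasTest(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  set.seed(131)
  t1 <- rnorm(60, 50, 5)
  t2 <- t1 + rnorm(60, 1, 1)   # shift delta = 1, sigma_d = 1
  expect_lt(pairedBiasTest(t1, t2)$p, 0.001)
  expect_error(pairedBiasTest(5, 6), class = "insufficientDataError")
  expect_error(pairedBiasTest(x, x + 2), class = "degenerateSampleError")
})

test_that("ICC(2,k) reproduces an independent reference and its invariances", {
  m <- matrix(c(10, 11, 12, 14, 9, 9.5, 15, 16, 8, 10, 13, 12),
              ncol = 2, byrow = TRUE)
  r <- icc2k(m)
  # reference values computed with an independent ICC implementation
  expect_equal(r$icc, 0.927349, tolerance = 1e-5)
  expect_equal(round(r$ci95, 2), c(0.44, 0.99))
  expect_identical(r$interpretation, "excellent")
  # duplicated occasions: perfect agreement
  dup <- icc2k(cbind(m[, 1], m[, 1]))
  expect_equal(dup$icc, 1)
  expect_equal(dup$ci95, c(1, 1))
  # permuting subjects leaves the ICC unchanged
  expect_equal(icc2k(m[sample(nrow(m)), ])$icc, r$icc, tolerance = 1e-12)
  # a constant offset on occasion 2 lowers absolute agreement
  shifted <- icc2k(cbind(m[, 1], m[, 2] + 5))
  expect_lt(shifted$icc, r$icc)
  expect_error(icc2k(m[1:2, ]), class = "insufficientDataError")
  mNA <- m; mNA[2, 1] <- NA
  expect_error(icc2k(mNA), class = "incompleteMatrixError")
  expect_error(icc2k(matrix(1, 5, 2)), class = "degenerateSampleError")
})

test_that("ICC estimate recovers the generating variance components", {
  set.seed(141)
  n <- 500
  true <- rnorm(n, 50, 10)
  m <- cbind(true + rnorm(n, 0, 3), true + rnorm(n, 0, 3))
  est <- icc2k(m)
  target <- expectedIcc2k(10, 3, k = 2)
  expect_lt(abs(est$icc - target), 0.02)
  expect_true(est$ci95[1] <= est$icc && est$icc <= est$ci95[2])
})

test_that("SEM and MDC follow the difference-based definitions", {
  x <- c(3, 7, 11, 2)
  expect_equal(semFromDiff(x, x), 0)
  expect_equal(semFromDiff(c(0, 0), c(1, -1)), 1)  # diffs {+1,-1}: SD sqrt(2)
  # pure systematic bias carries no random error
  expect_equal(semFromDiff(x, x + 4), 0)
  # invariant to adding the same constant to both occasions
  set.seed(151)
  a <- rnorm(30); b <- a + rnorm(30, 0, 2)
  expect_equal(semFromDiff(a + 7, b + 7), semFromDiff(a, b), tolerance = 1e-12)
  expect_equal(mdcFromSem(1), 2.7719, tolerance = 1e-4)
  expect_equal(mdcFromSem(0), 0)
  expect_error(mdcFromSem(-1), class = "invalidInputError")
})

test_that("validity and reliability reports assemble the full battery", {
  cohort <- simulateCohort(seed = 7)
  occ1 <- cohort[cohort$occasion == 1, ]
  v <- validityReport(occ1)
  expect_s3_class(v, "ValidityReport")
  expect_named(v$variables, c("acuity_pct", "speed_mm_s", "time_s",
                              "norm_acuity_au"))
  a <- v$variables$norm_acuity_au$anova
  expect_true(is.finite(a$F) && a$p >= 0 && a$p <= 1)
  expect_equal(nrow(a$posthoc), 3L)
  roc <- v$roc$norm_acuity_au
  expect_named(roc, c("NP_vs_CON", "INP_vs_CON", "TNP_vs_CON"))
  expect_true(all(vapply(roc, function(r) r$auc >= 0 && r$auc <= 1,
                         logical(1))))
  expect_named(v$ndi_correlations, c("INP", "TNP"))

  occ2 <- cohort[cohort$occasion == 2, ]
  rel <- reliabilityReport(occ1, occ2)
  expect_s3_class(rel, "ReliabilityReport")
  for (nm in names(rel$variables)) {
    x <- rel$variables[[nm]]
    expect_true(x$icc_ci95[1] <= x$icc && x$icc <= x$icc_ci95[2])
    expect_equal(x$mdc, x$sem * 1.96 * sqrt(2), tolerance = 1e-12)
  }
  expect_output(print(v), "ROC")
  expect_output(print(rel), "ICC")
})
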