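test_that("pair counts follow c(c-1)/2", {
  expect_equal(nPairs(18), 153)
  expect_equal(nPairs(2), 1)
  expect_equal(nPairs(5), 10)
  expect_error(nPairs(1), "at least 2")
})

test_that("the blocked ANOVA matches hand-computed decompositions", {
  t1 <- performanceTable(matrix(c(1, 2, 3, 4), 2, 2))  # [[1,3],[2,4]]
  a1 <- blockedAnova(t1)
  expect_equal(unname(a1@ss[c("split", "combo", "error", "total")]),
               c(1, 4, 0, 5))
  t2 <- performanceTable(matrix(c(1, 2, 2, 1), 2, 2))  # [[1,2],[2,1]]
  a2 <- blockedAnova(t2)
  expect_equal(unname(a2@ss[c("split", "combo", "error")]), c(0, 0, 1))
  expect_equal(unname(a2@df["error"]), 1)
  # location invariance
  a3 <- blockedAnova(performanceTable(matrix(c(1, 2, 3, 4), 2, 2) + 100))
  expect_equal(a3@ss, a1@ss)
  expect_equal(a3@pvalue, a1@pvalue)
  expect_error(blockedAnova(performanceTable(matrix(1:3, 3, 1))), "at least 2")
})

test_that("the closed-form ANOVA agrees with a least-squares additive fit", {
  set.seed(101)
  for (i in 1:10) {
    s <- sample(2:5, 1); cc <- sample(2:7, 1)
    Y <- matrix(rnorm(s * cc), s, cc)
    tbl <- performanceTable(Y)
    a <- blockedAnova(tbl)
    df <- data.frame(y = as.vector(Y),
                     split = factor(rep(seq_len(s), cc)),
                     combo = factor(rep(seq_len(cc), each = s)))
    fit <- stats::aov(y ~ split + combo, data = df)
    an <- summary(fit)[[1]]
    expect_equal(unname(a@ss["split"]), an["split", "Sum Sq"],
                 tolerance = 1e-8)
    expect_equal(unname(a@ss["combo"]), an["combo", "Sum Sq"],
                 tolerance = 1e-8)
    expect_equal(unname(a@ss["error"]), an["Residuals", "Sum Sq"],
                 tolerance = 1e-8)
    expect_equal(unname(a@pvalue["combo"]), an["combo", "Pr(>F)"],
                 tolerance = 1e-8)
    # exact additive decomposition
    expect_equal(unname(a@ss["split"] + a@ss["combo"] + a@ss["error"]),
                 unname(a@ss["total"]), tolerance = 1e-9)
    # effects sum to zero and reconstruct the cell means
    expect_equal(sum(a@splitEffects), 0, tolerance = 1e-10)
    expect_equal(sum(a@comboEffects), 0, tolerance = 1e-10)
  }
})

test_that("Tukey-Kramer p-values behave as a multiplicity adjustment", {
  set.seed(202)
  for (i in 1:20) {
    s <- sample(3:5, 1); cc <- sample(3:6, 1)
    tbl <- performanceTable(matrix(rnorm(s * cc), s, cc))
    a <- blockedAnova(tbl)
    comp <- tukeyKramer(tbl, a)
    pr <- pairwiseTable(comp)
    expect_equal(nrow(pr), nPairs(cc))
    expect_true(all(pr$p_adjusted >= 0 & pr$p_adjusted <= 1))
    # adjusted p >= unadjusted pooled-MSE t-test p, every pair
    tstat <- abs(pr$diff) / sqrt(2 * a@ms[["error"]] / s)
    pT <- 2 * pt(tstat, df = a@df[["error"]], lower.tail = FALSE)
    expect_true(all(pr$p_adjusted >= pT - 1e-12))
    # positive scaling leaves every p-value unchanged
    comp2 <- tukeyKramer(performanceTable(performanceValues(tbl) * 3.7), NULL)
    expect_equal(comp2@pairs$p_adjusted, pr$p_adjusted, tolerance = 1e-9)
  }
})

test_that("with two combinations Tukey-Kramer reduces to the paired t-test", {
  set.seed(303)
  for (i in 1:10) {
    s <- sample(3:8, 1)
    Y <- matrix(rnorm(2 * s), s, 2)
    comp <- tukeyKramer(performanceTable(Y))
    pt <- t.test(Y[, 1], Y[, 2], paired = TRUE)
    expect_equal(pairwiseTable(comp)$p_adjusted, pt$p.value, tolerance = 1e-6)
  }
})

test_that("identical columns compare as equivalent", {
  set.seed(7)
  base <- rnorm(4)
  Y <- cbind(a = base, b = base, c = rnorm(4))
  comp <- tukeyKramer(performanceTable(Y))
  pr <- pairwiseTable(comp)
  ab <- pr[pr$combo_a == "a" & pr$combo_b == "b", ]
  expect_equal(ab$diff, 0)
  expect_equal(ab$p_adjusted, 1)
})

test_that("a zero-MSE table degenerates to p in {0, 1} with a warning", {
  Y <- cbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(2, 3, 4))  # purely additive
  expect_warning(comp <- tukeyKramer(performanceTable(Y)), "MS_error is zero")
  pr <- pairwiseTable(comp)
  expect_equal(pr$p_adjusted[pr$combo_a == "a" & pr$combo_b == "b"], 1)
  expect_equal(pr$p_adjusted[pr$combo_a == "a" & pr$combo_b == "c"], 0)
})

test_that("the MCS matrix is symmetric, ordered best-to-worst, self on the diagonal", {
  tbl <- makePerformanceTable(s = 3, c = 6, sigma = 0.1,
                              elevated = list(index = 4, delta = 5), seed = 17)
  comp <- tukeyKramer(tbl)
  m <- mcsMatrix(comp)
  expect_identical(rownames(m)[1], "combo4")  # dominant combo ranks first
  expect_true(all(m[1, -1] == "p<=0.01"))     # and differs from all others
  expect_identical(m, t(m))
  expect_true(all(diag(m) == "self"))
  # orientation flips the ordering for smaller-is-better measures
  tblMin <- performanceTable(performanceValues(tbl), orientation = "minimize")
  compMin <- tukeyKramer(tblMin)
  expect_identical(comboOrdering(compMin), rev(comboOrdering(comp)))
})

test_that("a null table yields mostly non-significant categories", {
  tbl <- makePerformanceTable(s = 4, c = 5, sigma = 1, seed = 23)
  m <- mcsMatrix(tukeyKramer(tbl))
  off <- m[upper.tri(m)]
  expect_true(all(off == "p>0.05"))
})
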