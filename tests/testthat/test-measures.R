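test_that("thresholding uses the >= convention on any score scale", {
  expect_identical(thresholdScores(c(0.2, 0.5, 0.9), 0.5), c(0L, 1L, 1L))
  expect_identical(thresholdScores(c(0.2, 0.5, 0.9), -Inf), c(1L, 1L, 1L))
  expect_identical(thresholdScores(c(-1.2, 3.4), 0.5), c(0L, 1L))
})

test_that("confusion counts enumerate correctly", {
  cc <- confusionCounts(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_identical(cc, list(TP = 1L, FP = 1L, TN = 1L, FN = 1L))
  y <- c(1, 0, 1, 1, 0)
  same <- confusionCounts(y, y)
  expect_identical(same$FP + same$FN, 0L)
  comp <- confusionCounts(y, 1 - y)
  expect_identical(comp$TP + comp$TN, 0L)
  expect_error(confusionCounts(c(1, 0), c(1, 0, 1)), "lengths differ")
})

test_that("binary measures match their definitions, with NaN for 0/0", {
  m <- binaryMeasures(list(TP = 1L, FP = 1L, TN = 1L, FN = 1L))
  expect_equal(unlist(m), c(error_rate = 0.5, sens = 0.5, spec = 0.5,
                            ppv = 0.5, f1 = 0.5))
  # sens 0.5, ppv 1 -> harmonic mean 2/3
  m2 <- binaryMeasures(list(TP = 1L, FP = 0L, TN = 2L, FN = 1L))
  expect_equal(m2$f1, 2 / 3)
  expect_true(is.nan(binaryMeasures(list(TP = 0L, FP = 0L, TN = 3L, FN = 1L))$ppv))
  # identity: error_rate = 1 - accuracy, exactly
  set.seed(3)
  for (i in 1:20) {
    y <- rbinom(30, 1, 0.4); yh <- rbinom(30, 1, 0.5)
    cc <- confusionCounts(y, yh)
    expect_equal(binaryMeasures(cc)$error_rate, 1 - (cc$TP + cc$TN) / 30)
  }
})

test_that("AUC equals the Mann-Whitney pair-counting probability", {
  expect_equal(aucScore(c(1, 0), c(0.9, 0.1)), 1)
  expect_equal(aucScore(c(1, 0, 1, 0), rep(0.3, 4)), 0.5)
  expect_equal(aucScore(c(1, 1, 0, 0), c(0.9, 0.2, 0.8, 0.1)), 0.75)
  expect_error(aucScore(c(1, 1), c(0.1, 0.2)), "positive and one negative")
  set.seed(9)
  for (i in 1:50) {
    y <- c(1, 0, rbinom(18, 1, 0.4))
    s <- round(rnorm(20), 1)  # coarse scores force ties
    expect_equal(aucScore(y, s), bruteForceAuc(y, s))
    expect_equal(aucScore(y, s) + aucScore(y, -s), 1)
  }
})

test_that("initial enhancement follows the hit-rate-over-base-rate definition", {
  # perfect ranking assessed at m = p gives n/p
  y <- rep(c(1, 0), c(10, 90))
  s <- seq(100, 1)
  expect_equal(initialEnhancement(y, s, m = 10), 100 / 10)
  # one hit in the top 10 of n=100 with p=10: hit rate equals base rate
  y2 <- c(1, rep(0, 9), rep(1, 9), rep(0, 81))
  expect_equal(initialEnhancement(y2, seq(100, 1), m = 10), 1)
  # h=6 of m=20 against p/n = 0.1 -> 3
  y3 <- c(rep(1, 6), rep(0, 14), rep(1, 4), rep(0, 76))
  expect_equal(initialEnhancement(y3, seq(100, 1), m = 20), 3)
  expect_error(initialEnhancement(y, s, m = 101), "exceed")
  expect_error(initialEnhancement(rep(0, 10), 1:10, m = 5), "positive")
})

test_that("IE is invariant under strictly monotone score transforms", {
  set.seed(31)
  for (i in 1:20) {
    y <- rbinom(50, 1, 0.2); if (!sum(y)) y[1] <- 1
    s <- rnorm(50)
    base <- initialEnhancement(y, s, m = 12)
    expect_equal(initialEnhancement(y, 3 * s + 7, m = 12), base)
    expect_equal(initialEnhancement(y, exp(s), m = 12), base)
  }
})

test_that("continuous measures match their definitions", {
  y <- c(1, 2, 3, 4)
  expect_equal(unlist(continuousMeasures(y, y)),
               c(rmse = 0, r2 = 1, spearman = 1))
  expect_equal(continuousMeasures(y, rep(mean(y), 4))$r2, 0)
  expect_equal(continuousMeasures(c(1, 2, 3), c(3, 2, 1))$spearman, -1)
  flat <- continuousMeasures(rep(2, 3), c(1, 2, 3))
  expect_true(is.nan(flat$r2) && is.nan(flat$spearman))
  expect_equal(continuousMeasures(c(0, 0, 2), c(1, 1, 1))$rmse, 1)
})

test_that("the performance table is splits x combinations and complete", {
  store <- tinyStore(n = 60, nPos = 15, splits = 3,
                     sets = c("A", "B"),
                     methods = paste0("m", 1:9))
  tbl <- buildPerformanceTable(store, "auc")
  expect_identical(dim(performanceValues(tbl)), c(3L, 18L))
  expect_identical(measureOrientation(tbl), "maximize")
  expect_false(anyNA(performanceValues(tbl)))
  # IE default m is capped at n
  tb2 <- buildPerformanceTable(store, "ie")
  expect_equal(tb2@m, 60)
  expect_error(buildPerformanceTable(store, "rmse"), "continuous")
  cstore <- tinyStore(n = 30, splits = 2, responseType = "continuous")
  expect_error(buildPerformanceTable(cstore, "auc"), "binary")
  expect_error(buildPerformanceTable(store, "gini"), "unknown measure")
})

test_that("combinations with undefined measure values are dropped whole", {
  store <- tinyStore(n = 20, nPos = 5, splits = 2, sets = "A",
                     methods = c("good", "allneg"))
  # make 'allneg' predict nothing positive in split 1 -> PPV is 0/0
  store@entries[["1|A|allneg"]] <- rep(-1, 20)
  expect_warning(tbl <- buildPerformanceTable(store, "ppv", threshold = 0.5),
                 "dropping")
  expect_identical(colnames(performanceValues(tbl)), "A_good")
})
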