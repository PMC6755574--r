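test_that("the registry exposes exactly 13 methods with the stated capabilities", {
  m <- listMethods()
  expect_length(m, 13L)
  expect_setequal(m, c("ENet", "KNN", "Lasso", "LAR", "NNet", "PLSLDA", "PLS",
                       "PCR", "Ridge", "RF", "Tree", "RPart", "SVM"))
  native <- c("Tree", "RPart", "RF", "KNN", "NNet", "SVM")
  asCont <- c("Lasso", "LAR", "Ridge", "ENet", "PCR", "PLS")
  for (mm in native) {
    info <- methodInfo(mm)
    expect_true(info$supportsBinary && info$supportsContinuous)
    expect_false(info$treatsBinaryAsContinuous)
  }
  for (mm in asCont) expect_true(methodInfo(mm)$treatsBinaryAsContinuous)
  expect_false(methodInfo("PLSLDA")$supportsContinuous)
  expect_error(methodInfo("GBM"), "unregistered")
})

test_that("defaults registry has 13 entries and unknown parameters are rejected", {
  p <- makeModelDefaults()
  expect_length(p, 13L)
  expect_setequal(names(p), listMethods())
  X <- matrix(rnorm(40), 20, 2)
  y <- rep(c(0, 1), 10)
  expect_error(fitPredict("KNN", X, y, X, params = list(neighbors = 3),
                          responseType = "binary"),
               "unrecognized parameter")
})

test_that("changing one method's parameters leaves other methods untouched", {
  d <- makeBinaryDataset(n = 40, nActive = 12, nContinuousDesc = 4,
                         nBinaryDesc = 3, effect = 1, seed = 8)
  plan <- makeCvPlan(40, nsplits = 1, nfolds = 4)
  p1 <- makeModelDefaults()
  p2 <- makeModelDefaults(); p2$KNN$k <- 3
  s1 <- runRepeatedCV(d, methods = c("KNN", "Tree"), plan = plan, params = p1)
  s2 <- runRepeatedCV(d, methods = c("KNN", "Tree"), plan = plan, params = p2)
  expect_false(identical(getPredictions(s1, 1, "ContinuousSet", "KNN"),
                         getPredictions(s2, 1, "ContinuousSet", "KNN")))
  expect_identical(getPredictions(s1, 1, "ContinuousSet", "Tree"),
                   getPredictions(s2, 1, "ContinuousSet", "Tree"))
})

test_that("1-NN returns the response of an identical training row", {
  X <- matrix(c(0, 0, 1, 1, 5, 5), 3, 2, byrow = TRUE)
  y <- c(0, 1, 0)
  pred <- fitPredict("KNN", X, y, X[2, , drop = FALSE],
                     params = list(k = 1), responseType = "binary")
  expect_equal(pred, 1)
})

test_that("a constant training response makes every method predict the constant", {
  set.seed(4)
  X <- matrix(rnorm(30), 15, 2)
  Xt <- matrix(rnorm(6), 3, 2)
  for (m in listMethods()) {
    expect_equal(fitPredict(m, X, rep(1, 15), Xt, responseType = "binary"),
                 rep(1, 3), info = m)
    if (methodInfo(m)$supportsContinuous)
      expect_equal(fitPredict(m, X, rep(2.5, 15), Xt,
                              responseType = "continuous"),
                   rep(2.5, 3), info = m)
  }
})

test_that("least-squares methods on a binary response are not clipped to [0,1]", {
  # well-separated data: a gaussian-loss linear fit must overshoot [0, 1]
  set.seed(10)
  x <- c(rnorm(20, -3), rnorm(20, 3))
  X <- cbind(x, rnorm(40))
  y <- rep(c(0, 1), each = 20)
  test <- rbind(c(-5, 0), c(5, 0), c(0, 0))
  for (m in c("Lasso", "Ridge", "ENet", "PCR", "PLS", "LAR")) {
    prep <- preprocessFor(m, X, test)
    sc <- fitPredict(m, prep$train, y, prep$test, responseType = "binary",
                     seed = 2)
    expect_true(any(sc < 0 | sc > 1), info = m)
  }
})

test_that("PLSLDA needs a dichotomizing threshold on continuous responses", {
  set.seed(6)
  X <- matrix(rnorm(60), 30, 2)
  y <- X[, 1] + rnorm(30, sd = 0.2)
  expect_error(fitPredict("PLSLDA", X, y, X, responseType = "continuous"),
               "threshold")
  sc <- fitPredict("PLSLDA", X, y, X, responseType = "continuous",
                   responseThreshold = median(y))
  expect_true(all(sc >= 0 & sc <= 1))
  # should broadly separate the dichotomized classes
  expect_gt(aucScore(as.numeric(y >= median(y)), sc), 0.8)
})

test_that("natively classifying methods return probabilities in [0, 1]", {
  d <- makeBinaryDataset(n = 40, nActive = 15, nContinuousDesc = 4,
                         nBinaryDesc = 3, effect = 1.5, seed = 12)
  X <- descriptorSets(d)$ContinuousSet
  y <- responseValues(d)
  params <- makeModelDefaults()
  params$RF$ntree <- 10; params$NNet$maxit <- 30
  for (m in c("KNN", "Tree", "RPart", "RF", "NNet", "SVM", "PLSLDA")) {
    prep <- preprocessFor(m, X, X)
    sc <- fitPredict(m, prep$train, y, prep$test, params = params[[m]],
                     responseType = "binary", seed = 3)
    expect_true(all(sc >= 0 & sc <= 1), info = m)
    expect_gt(aucScore(y, sc), 0.7)  # resubstitution: signal must be found
  }
})

test_that("standardization uses training statistics only", {
  trainX <- matrix(c(3, 5, 7, 1, 1, 1), 3, 2)  # col1 mean 5 sd 2, col2 zero-var
  testX <- matrix(c(9, 4), 1, 2)
  out <- preprocessFor("PCR", trainX, testX)
  expect_equal(out$test[1, 1], 2)          # (9 - 5) / 2
  expect_equal(out$test[1, 2], 3)          # centered by 1, scale forced to 1
  expect_equal(unname(colMeans(out$train)), c(0, 0))
  # translating the test rows never changes the fitted training block
  out2 <- preprocessFor("PCR", trainX, testX + 100)
  expect_identical(out$train, out2$train)
  # tree-based methods pass through unchanged
  expect_identical(preprocessFor("RF", trainX, testX)$train, trainX)
  expect_identical(preprocessFor("Tree", trainX, testX)$test, testX)
})

test_that("deterministic methods are invariant to training-row permutation", {
  set.seed(14)
  X <- matrix(rnorm(60), 20, 3)
  y <- rnorm(20) + X[, 1]
  Xt <- matrix(rnorm(9), 3, 3)
  perm <- sample(20)
  for (m in c("PCR", "PLS", "Tree")) {
    a <- fitPredict(m, X, y, Xt, responseType = "continuous", seed = 1)
    b <- fitPredict(m, X[perm, ], y[perm], Xt, responseType = "continuous",
                    seed = 1)
    expect_equal(a, b, tolerance = 1e-8, info = m)
  }
})

test_that("degenerate fits fall back to the mean response with a warning", {
  # a single descriptor that is constant defeats the LDA step of PLSLDA
  X <- matrix(1, 10, 1)
  y <- rep(c(0, 1), 5)
  expect_warning(
    sc <- fitPredict("PLSLDA", X, y, X, responseType = "binary"),
    "falling back")
  expect_equal(sc, rep(0.5, 10))
})
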