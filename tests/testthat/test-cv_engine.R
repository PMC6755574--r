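test_that("default seeds follow the 11111 * i convention", {
  expect_identical(defaultSeeds(1), 11111L)
  expect_identical(defaultSeeds(2), c(11111L, 22222L))
  expect_identical(defaultSeeds(4), c(11111L, 22222L, 33333L, 44444L))
  expect_error(defaultSeeds(0), "positive integer")
})

test_that("fold assignment is balanced, labeled 1..k and seeded", {
  f <- assignFolds(10, 5, seed = 1)
  expect_identical(sort(unique(f)), 1:5)
  expect_true(all(tabulate(f, 5) == 2L))

  f2 <- assignFolds(11, 5, seed = 1)
  expect_identical(sort(tabulate(f2, 5)), c(2L, 2L, 2L, 2L, 3L))

  expect_identical(assignFolds(30, 4, seed = 9), assignFolds(30, 4, seed = 9))
  expect_false(identical(assignFolds(30, 4, seed = 9),
                         assignFolds(30, 4, seed = 10)))
  expect_error(assignFolds(5, 6, seed = 1), "2 <= k <= n")
  expect_error(assignFolds(5, 1, seed = 1), "2 <= k <= n")
})

test_that("folds partition 1..n with balanced sizes across random cases", {
  set.seed(77)
  for (i in 1:25) {
    n <- sample(10:200, 1)
    k <- sample(2:min(10, n), 1)
    f <- assignFolds(n, k, seed = sample.int(1e6, 1))
    expect_length(f, n)
    expect_true(all(f %in% seq_len(k)))
    sz <- tabulate(f, k)
    expect_true(all(sz %in% c(n %/% k, n %/% k + 1L)))
    expect_identical(sum(sz), n)
  }
})

test_that("repeated CV yields one out-of-fold prediction per observation and key", {
  d <- makeBinaryDataset(n = 50, nActive = 15, nContinuousDesc = 4,
                         nBinaryDesc = 4, effect = 1, seed = 3)
  plan <- makeCvPlan(50, nsplits = 2, nfolds = 5)
  store <- runRepeatedCV(d, methods = c("KNN", "Tree", "PCR"), plan = plan)
  expect_length(predictionKeys(store), 2 * 2 * 3)
  for (k in predictionKeys(store))
    expect_length(store@entries[[k]], 50L)
  # blocking: assignments reused verbatim across combinations within a split
  expect_identical(foldAssignments(plan, 1), plan@assignments[[1]])
})

test_that("a full run is bit-reproducible, including stochastic methods", {
  d <- makeBinaryDataset(n = 40, nActive = 12, nContinuousDesc = 4,
                         nBinaryDesc = 3, effect = 1, seed = 5)
  plan <- makeCvPlan(40, nsplits = 1, nfolds = 4)
  params <- makeModelDefaults()
  params$RF$ntree <- 10
  params$NNet$maxit <- 30
  s1 <- runRepeatedCV(d, methods = c("RF", "NNet", "KNN"), plan = plan,
                      params = params)
  s2 <- runRepeatedCV(d, methods = c("RF", "NNet", "KNN"), plan = plan,
                      params = params)
  expect_identical(s1@entries, s2@entries)
})

test_that("held-out predictions are reproduced by refitting without the fold", {
  d <- makeBinaryDataset(n = 45, nActive = 15, nContinuousDesc = 5,
                         nBinaryDesc = 3, effect = 1, seed = 11)
  plan <- makeCvPlan(45, nsplits = 1, nfolds = 3)
  store <- runRepeatedCV(d, methods = "KNN", plan = plan)
  X <- do.call(cbind, descriptorSets(d))
  # same matrix the engine used for set 1? refit per set instead:
  for (setName in descriptorSetNames(d)) {
    Xs <- descriptorSets(d)[[setName]]
    y <- responseValues(d)
    folds <- foldAssignments(plan, 1)
    stored <- getPredictions(store, 1, setName, "KNN")
    for (f in 1:3) {
      test <- folds == f
      prep <- preprocessFor("KNN", Xs[!test, , drop = FALSE],
                            Xs[test, , drop = FALSE])
      refit <- fitPredict("KNN", prep$train, y[!test], prep$test,
                          params = list(k = 10), responseType = "binary")
      expect_equal(stored[test], refit, tolerance = 1e-12)
    }
  }
})

test_that("1-NN recovers the response of a duplicated training row", {
  set.seed(21)
  base <- matrix(rnorm(20 * 3), 20, 3)
  X <- rbind(base, base)  # every row duplicated
  y <- c(rep(c(0, 1), 10), rep(c(0, 1), 10))
  d <- makeModelingDataset(X, y, responseType = "binary")
  plan <- makeCvPlan(40, nsplits = 1, nfolds = 2)
  params <- makeModelDefaults(); params$KNN$k <- 1
  store <- runRepeatedCV(d, methods = "KNN", plan = plan, params = params)
  pred <- getPredictions(store, 1, "descriptors", "KNN")
  folds <- foldAssignments(plan, 1)
  for (i in 1:20) {
    j <- i + 20  # duplicate partner
    if (folds[i] != folds[j]) {
      # each one's duplicate sits in the training half
      expect_equal(pred[i], y[j])
      expect_equal(pred[j], y[i])
    }
  }
})

test_that("incompatible or failing combinations are skipped with a warning", {
  d <- makeContinuousDataset(n = 30, nDesc = 4, seed = 2)
  plan <- makeCvPlan(30, nsplits = 1, nfolds = 3)
  expect_warning(
    store <- runRepeatedCV(d, methods = c("PLSLDA", "PCR"), plan = plan),
    "PLSLDA")
  expect_identical(predictionKeys(store), "1|descriptors|PCR")
  expect_match(names(store@failures), "PLSLDA")
})
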