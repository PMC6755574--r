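# The 13-method modeling suite: registry, defaults, preprocessing and the
# uniform fit/predict contract.
#
# Backends: glmnet (ENet/Lasso/Ridge), FNN (KNN), MASS::lda (the LDA step of
# PLSLDA).  CART trees, the random forest, the single-hidden-layer neural
# net, SIMPLS partial least squares, principal components regression, least
# angle regression and the radial-kernel SVM-type learner are implemented in
# this package (see learners-*.R).

.methodTable <- data.frame(
  name = c("ENet", "KNN", "Lasso", "LAR", "NNet", "PLSLDA", "PLS",
           "PCR", "Ridge", "RF", "Tree", "RPart", "SVM"),
  supportsBinary = TRUE,
  supportsContinuous = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE,
                         TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
  treatsBinaryAsContinuous = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE,
                               TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
  needsStandardization = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                           TRUE, TRUE, FALSE, FALSE, FALSE, TRUE),
  stringsAsFactors = FALSE
)

#' List the registered modeling methods
#'
#' @return character vector of the 13 method names.
#' @export
listMethods <- function() .methodTable$name

#' Describe a registered method
#'
#' @param method method name.
#' @return a one-row data.frame with the method's capability flags:
#'   \code{supportsBinary}, \code{supportsContinuous},
#'   \code{treatsBinaryAsContinuous} (the six linear least-squares methods
#'   that model a 0/1 response as continuous, yielding unbounded scores) and
#'   \code{needsStandardization}.
#' @export
methodInfo <- function(method) {
  row <- .methodTable[.methodTable$name == method, ]
  if (!nrow(row)) stop("unregistered method: ", method)
  row
}

#' Default hyperparameters for all 13 methods
#'
#' Returns a named list (one entry per method) of default tuning parameters.
#' Modify entries and pass the list to \code{\link{runRepeatedCV}} to override
#' defaults; changing one method's parameters never affects another method.
#'
#' Defaults: KNN 10 neighbors; RF 100 trees with per-node feature sampling
#' (mtry = sqrt(p) for classification, p/3 for regression); SVM radial kernel
#' with cost 1 and gamma 1/p; NNet one hidden layer of size 2 with weight
#' decay 0.1; Lasso/Ridge/ENet penalty chosen by an internal 5-fold grid on
#' the training fold; LAR step count chosen the same way (at most
#' \code{max.steps}); PCR/PLS/PLSLDA at most 10 components (capped at the
#' matrix rank); Tree is a deep, lightly penalized CART and RPart a shallower,
#' cost-complexity-pruned CART.
#'
#' @return named list of per-method parameter lists.
#' @examples
#' p <- makeModelDefaults()
#' p$KNN$k <- 5
#' @export
makeModelDefaults <- function() {
  list(
    ENet   = list(alpha = 0.5, lambda = "cv"),
    KNN    = list(k = 10),
    Lasso  = list(lambda = "cv"),
    LAR    = list(max.steps = 20),
    NNet   = list(size = 2, decay = 0.1, maxit = 150),
    PLSLDA = list(ncomp = 10),
    PLS    = list(ncomp = 10),
    PCR    = list(ncomp = 10),
    Ridge  = list(lambda = "cv"),
    RF     = list(ntree = 100, mtry = NA, minsplit = 5, maxdepth = 12),
    Tree   = list(minsplit = 5, maxdepth = 10, cp = 0.001),
    RPart  = list(minsplit = 20, maxdepth = 30, cp = 0.01),
    SVM    = list(cost = 1, gamma = NA)
  )
}

#' Center and scale descriptors using training-fold statistics only
#'
#' Methods flagged \code{needsStandardization} (PCR, PLS, PLSLDA, Ridge,
#' Lasso, LAR, ENet, KNN, SVM, NNet) receive columns centered and scaled by
#' the training mean and standard deviation; zero-variance training columns
#' are centered with scale factor 1.  Tree-based methods (Tree, RPart, RF)
#' pass through unchanged.  No statistic ever uses held-out rows.
#'
#' @param method method name.
#' @param trainX,testX numeric matrices with equal column counts.
#' @return list with elements \code{train} and \code{test}.
#' @export
preprocessFor <- function(method, trainX, testX) {
  info <- methodInfo(method)
  if (!info$needsStandardization)
    return(list(train = trainX, test = testX))
  mu <- colMeans(trainX)
  sdv <- apply(trainX, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(train = scale(trainX, center = mu, scale = sdv)[, , drop = FALSE],
       test = scale(testX, center = mu, scale = sdv)[, , drop = FALSE])
}

#' Fit one method on training data and score test rows
#'
#' The uniform fit/predict contract.  For a binary response: natively
#' classifying methods (Tree, RPart, RF, KNN, NNet, SVM, PLSLDA) return
#' predicted probabilities of class 1 in [0, 1]; the six least-squares
#' methods (Lasso, LAR, Ridge, ENet, PCR, PLS) treat the 0/1 response as
#' continuous and return unbounded real scores that are never clipped.  For
#' a continuous response all methods return real-valued predictions.  Higher
#' score always means predicted-more-active.
#'
#' A degenerate fit (singular system, optimizer failure) falls back to
#' predicting the training-mean response with a warning rather than aborting
#' a run.
#'
#' @param method registered method name.
#' @param trainX,trainY training descriptors and response.
#' @param testX rows to score (same column count as \code{trainX}).
#' @param params parameter list for this method (see
#'   \code{\link{makeModelDefaults}}); missing entries take defaults.
#' @param responseType \code{"binary"} or \code{"continuous"}.
#' @param responseThreshold threshold dichotomizing a continuous response,
#'   required by PLSLDA on continuous data.
#' @param seed integer seed for the method's internal randomness (bootstrap,
#'   weight initialization, internal tuning folds).
#' @return numeric score vector, one per test row.
#' @export
fitPredict <- function(method, trainX, trainY, testX, params = NULL,
                       responseType = c("binary", "continuous"),
                       responseThreshold = NA_real_, seed = 1L) {
  responseType <- match.arg(responseType)
  info <- methodInfo(method)
  trainX <- as.matrix(trainX); testX <- as.matrix(testX)
  if (ncol(trainX) != ncol(testX))
    stop("train and test column counts differ")
  if (nrow(trainX) != length(trainY))
    stop("trainX rows and trainY length differ")

  defaults <- makeModelDefaults()[[method]]
  if (is.null(params)) params <- list()
  bad <- setdiff(names(params), names(defaults))
  if (length(bad))
    stop("unrecognized parameter(s) for ", method, ": ",
         paste(bad, collapse = ", "))
  params <- utils::modifyList(defaults, params)

  if (responseType == "continuous" && !info$supportsContinuous) {
    if (is.na(responseThreshold))
      stop(method, " cannot be applied to a continuous response; supply a ",
           "response-dichotomizing threshold")
    trainY <- as.numeric(trainY >= responseThreshold)
    if (length(unique(trainY)) < 2L)
      stop("response threshold leaves a single class for ", method)
    responseType <- "binary"
  }

  # Degenerate training response: every method predicts the constant
  # (probability c for classifiers).
  if (length(unique(trainY)) == 1L)
    return(rep(trainY[1], nrow(testX)))

  binary <- responseType == "binary" && !info$treatsBinaryAsContinuous
  fit <- tryCatch(
    withSeed(seed, learnerFor(method)(trainX, trainY, testX, params, binary)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    warning(method, " fit failed (", conditionMessage(fit),
            "); falling back to the mean response", call. = FALSE)
    return(rep(mean(trainY), nrow(testX)))
  }
  as.numeric(fit)
}

learnerFor <- function(method) {
  switch(method,
    ENet = function(X, y, tX, p, b) glmnetScore(X, y, tX, alpha = p$alpha, lambda = p$lambda),
    Lasso = function(X, y, tX, p, b) glmnetScore(X, y, tX, alpha = 1, lambda = p$lambda),
    Ridge = function(X, y, tX, p, b) glmnetScore(X, y, tX, alpha = 0, lambda = p$lambda),
    LAR = function(X, y, tX, p, b) larScore(X, y, tX, maxSteps = p$max.steps),
    PCR = function(X, y, tX, p, b) pcrScore(X, y, tX, ncomp = p$ncomp),
    PLS = function(X, y, tX, p, b) plsScore(X, y, tX, ncomp = p$ncomp),
    PLSLDA = function(X, y, tX, p, b) plsLdaScore(X, y, tX, ncomp = p$ncomp),
    KNN = function(X, y, tX, p, b) knnScore(X, y, tX, k = p$k, binary = b),
    NNet = function(X, y, tX, p, b) nnetScore(X, y, tX, size = p$size,
                                              decay = p$decay, maxit = p$maxit,
                                              binary = b),
    SVM = function(X, y, tX, p, b) svmScore(X, y, tX, cost = p$cost,
                                            gamma = p$gamma, binary = b),
    Tree = function(X, y, tX, p, b) cartScore(X, y, tX, minsplit = p$minsplit,
                                              maxdepth = p$maxdepth, cp = p$cp),
    RPart = function(X, y, tX, p, b) cartScore(X, y, tX, minsplit = p$minsplit,
                                               maxdepth = p$maxdepth, cp = p$cp),
    RF = function(X, y, tX, p, b) rfScore(X, y, tX, ntree = p$ntree,
                                          mtry = p$mtry, minsplit = p$minsplit,
                                          maxdepth = p$maxdepth, binary = b),
    stop("unregistered method: ", method)
  )
}
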