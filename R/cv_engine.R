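# Seeded repeated k-fold cross-validation shared by all descriptor-set/method
# combinations: the fold assignment is the blocking factor of the downstream
# ANOVA, so it is built once per split and reused verbatim.

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Default cross-validation seeds
#'
#' With seeds unspecified, split i uses seed 11111 * i: the first split uses
#' 11111, the second 22222, and so on.
#'
#' @param nsplits number of cross-validation splits (>= 1).
#' @return integer vector of length \code{nsplits}.
#' @examples defaultSeeds(3)
#' @export
defaultSeeds <- function(nsplits) {
  if (!is.numeric(nsplits) || length(nsplits) != 1L || nsplits < 1 ||
      nsplits != round(nsplits))
    stop("'nsplits' must be a positive integer")
  as.integer(11111L * seq_len(nsplits))
}

#' Assign observations to k approximately equal folds
#'
#' A seeded uniform permutation of 1..n is dealt round-robin into k folds, so
#' every fold has floor(n/k) or ceil(n/k) members.
#'
#' @param n observation count.
#' @param k fold count, 2 <= k <= n.
#' @param seed integer RNG seed; the same (n, k, seed) always yields the same
#'   assignment.
#' @return integer vector of fold labels in 1..k.
#' @export
assignFolds <- function(n, k, seed) {
  if (k < 2 || k > n) stop("'k' must satisfy 2 <= k <= n")
  labels <- integer(n)
  labels[withSeed(seed, sample.int(n))] <- rep_len(seq_len(k), n)
  labels
}

#' Build a cross-validation plan
#'
#' @param n observation count (or a \linkS4class{ModelingDataset}).
#' @param nsplits number of repeated splits (default 3).
#' @param nfolds folds per split (default 10, reduced to n if larger).
#' @param seeds integer seed per split; defaults to
#'   \code{\link{defaultSeeds}(nsplits)}.
#' @return a \linkS4class{CvPlan}.
#' @export
makeCvPlan <- function(n, nsplits = 3L, nfolds = 10L, seeds = NULL) {
  if (is(n, "ModelingDataset")) n <- nObs(n)
  if (is.null(seeds)) seeds <- defaultSeeds(nsplits)
  if (length(seeds) != nsplits) stop("'seeds' must have length nsplits")
  assignments <- lapply(seeds, function(s) assignFolds(n, nfolds, s))
  new("CvPlan", nobs = as.integer(n), nfolds = as.integer(nfolds),
      seeds = as.integer(seeds), assignments = assignments)
}

# Deterministic per-combination seed derived from the split seed; kept under
# 2^31 for R's 32-bit integers.
comboSeed <- function(splitSeed, setIdx, methodIdx) {
  as.integer((as.double(splitSeed) * 97L + setIdx * 13L + methodIdx) %% 2147483647)
}

#' Run repeated k-fold cross-validation over all D-M combinations
#'
#' For every (split, descriptor set, method) combination, trains on k-1 folds
#' and predicts the held-out fold until every observation has one out-of-fold
#' predicted score.  All combinations within a split share the identical fold
#' assignment from the plan, and preprocessing statistics (centering/scaling)
#' are fitted on training folds only.
#'
#' @param data a \linkS4class{ModelingDataset}.
#' @param methods character vector of registered method names (see
#'   \code{\link{listMethods}}); default all compatible methods.
#' @param plan a \linkS4class{CvPlan}; default
#'   \code{makeCvPlan(nObs(data))}.
#' @param params a parameter registry from \code{\link{makeModelDefaults}},
#'   possibly modified.
#' @param responseThreshold optional threshold dichotomizing a continuous
#'   response for PLSLDA.
#' @return a \linkS4class{PredictionStore}.  Combinations whose fit fails or
#'   that are incompatible with the response type are skipped with a warning
#'   and recorded in the store's \code{failures} slot.
#' @export
runRepeatedCV <- function(data, methods = NULL, plan = NULL, params = NULL,
                          responseThreshold = NA_real_) {
  stopifnot(is(data, "ModelingDataset"))
  if (is.null(plan)) plan <- makeCvPlan(nObs(data))
  if (nObs(plan) != nObs(data)) stop("plan was built for a different n")
  if (is.null(params)) params <- makeModelDefaults()
  if (is.null(methods)) {
    methods <- listMethods()
    if (responseType(data) == "continuous" && is.na(responseThreshold))
      methods <- setdiff(methods, "PLSLDA")
  }
  unknown <- setdiff(methods, listMethods())
  if (length(unknown))
    stop("unregistered method(s): ", paste(unknown, collapse = ", "))

  y <- responseValues(data)
  sets <- descriptorSets(data)
  entries <- list()
  failures <- character()

  for (s in seq_along(plan@seeds)) {
    folds <- plan@assignments[[s]]
    for (d in seq_along(sets)) {
      X <- sets[[d]]
      for (mi in seq_along(methods)) {
        meth <- methods[[mi]]
        key <- storeKey(s, names(sets)[d], meth)
        seed <- comboSeed(plan@seeds[s], d, mi)
        pred <- tryCatch(
          cvOneCombo(X, y, folds, plan@nfolds, meth,
                     params[[meth]], responseType(data),
                     responseThreshold, seed),
          error = function(e) e
        )
        if (inherits(pred, "error")) {
          warning("skipping split ", s, " / ", names(sets)[d], " / ", meth,
                  ": ", conditionMessage(pred), call. = FALSE)
          failures[[key]] <- conditionMessage(pred)
        } else {
          entries[[key]] <- pred
        }
      }
    }
  }
  new("PredictionStore", entries = entries,
      splits = seq_along(plan@seeds),
      setNames = names(sets), methodNames = methods,
      ids = observationIds(data), observed = y,
      responseType = responseType(data), failures = failures)
}

# One (split, set, method): loop the folds, preprocess on training rows only,
# fit and score the held-out rows.
cvOneCombo <- function(X, y, folds, k, method, params, responseType,
                       responseThreshold, seed) {
  n <- length(y)
  pred <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    test <- which(folds == f)
    train <- which(folds != f)
    prep <- preprocessFor(method, X[train, , drop = FALSE],
                          X[test, , drop = FALSE])
    pred[test] <- fitPredict(method, prep$train, y[train], prep$test,
                             params = params, responseType = responseType,
                             responseThreshold = responseThreshold,
                             seed = seed + f)
  }
  if (anyNA(pred)) stop("internal error: incomplete out-of-fold predictions")
  pred
}
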