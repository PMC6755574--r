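#' @import methods
NULL

#' ModelingDataset: IDs, response and named descriptor sets
#'
#' The core data container.  Holds observation identifiers, a response vector
#' (binary coded 0/1, or continuous with larger = more active) and an ordered
#' list of named descriptor matrices (the descriptor sets).  All descriptor
#' matrices share the row order of the response; missing values are rejected
#' at construction.
#'
#' @slot ids character vector of observation identifiers (length n).
#' @slot response numeric vector of length n.
#' @slot descriptorSets named list of numeric matrices, each with n rows.
#' @slot responseType either \code{"binary"} or \code{"continuous"}.
#' @export
setClass("ModelingDataset",
  representation(
    ids = "character",
    response = "numeric",
    descriptorSets = "list",
    responseType = "character"
  )
)

setValidity("ModelingDataset", function(object) {
  msg <- character()
  n <- length(object@response)
  if (n < 2L) msg <- c(msg, "at least 2 observations are required")
  if (length(object@ids) != n)
    msg <- c(msg, "ids and response lengths differ")
  if (anyNA(object@response)) msg <- c(msg, "response contains missing values")
  if (!object@responseType %in% c("binary", "continuous"))
    msg <- c(msg, "responseType must be 'binary' or 'continuous'")
  if (object@responseType == "binary") {
    if (!all(object@response %in% c(0, 1)))
      msg <- c(msg, "binary response must contain only 0 and 1")
    else if (length(unique(object@response)) < 2L)
      msg <- c(msg, "binary response needs at least one 0 and one 1")
  }
  sets <- object@descriptorSets
  if (length(sets) < 1L) msg <- c(msg, "at least one descriptor set is required")
  nm <- names(sets)
  if (is.null(nm) || any(!nzchar(nm)))
    msg <- c(msg, "descriptor sets must have non-empty names")
  else if (anyDuplicated(nm))
    msg <- c(msg, "descriptor-set names must be unique")
  for (i in seq_along(sets)) {
    x <- sets[[i]]
    if (!is.matrix(x) || !is.numeric(x)) {
      msg <- c(msg, sprintf("descriptor set %d is not a numeric matrix", i))
      next
    }
    if (nrow(x) != n)
      msg <- c(msg, sprintf("descriptor set '%s' has %d rows, expected %d",
                            nm[i], nrow(x), n))
    if (anyNA(x))
      msg <- c(msg, sprintf("descriptor set '%s' contains missing values", nm[i]))
  }
  if (length(msg)) msg else TRUE
})

#' CvPlan: seeded repeated k-fold assignments
#'
#' Fold assignments for each cross-validation split.  All descriptor-set /
#' method combinations evaluated under a plan share these assignments, making
#' the split a blocking factor in the downstream ANOVA.
#'
#' @slot nobs number of observations the plan was built for.
#' @slot nfolds folds per split (k).
#' @slot seeds integer seed per split.
#' @slot assignments list (one element per split) of integer fold labels in 1..k.
#' @export
setClass("CvPlan",
  representation(
    nobs = "integer",
    nfolds = "integer",
    seeds = "integer",
    assignments = "list"
  )
)

setValidity("CvPlan", function(object) {
  msg <- character()
  s <- length(object@seeds)
  if (s < 1L) msg <- c(msg, "at least one split is required")
  if (length(object@assignments) != s)
    msg <- c(msg, "one assignment vector per seed is required")
  k <- object@nfolds
  n <- object@nobs
  if (k < 2L || k > n) msg <- c(msg, "nfolds must satisfy 2 <= k <= n")
  for (i in seq_along(object@assignments)) {
    a <- object@assignments[[i]]
    if (length(a) != n) {
      msg <- c(msg, sprintf("split %d assignment has wrong length", i))
      next
    }
    if (!all(a %in% seq_len(k)))
      msg <- c(msg, sprintf("split %d has fold labels outside 1..k", i))
    sz <- tabulate(a, nbins = k)
    if (!all(sz %in% c(n %/% k, n %/% k + (n %% k > 0L))))
      msg <- c(msg, sprintf("split %d fold sizes are unbalanced", i))
  }
  if (length(msg)) msg else TRUE
})

#' PredictionStore: out-of-fold predicted scores
#'
#' Holds, for every (split, descriptor set, method) combination that ran,
#' the n out-of-fold predicted scores aligned to observation order, plus the
#' observed response they are assessed against.
#'
#' @slot entries named list; key \code{"<split>|<set>|<method>"}, value a
#'   numeric vector of length n.
#' @slot splits integer vector of split indices present.
#' @slot setNames,methodNames character vectors of the descriptor sets and
#'   methods requested.
#' @slot ids observation identifiers.
#' @slot observed observed response.
#' @slot responseType \code{"binary"} or \code{"continuous"}.
#' @slot failures named character vector of error messages for combinations
#'   that were skipped.
#' @export
setClass("PredictionStore",
  representation(
    entries = "list",
    splits = "integer",
    setNames = "character",
    methodNames = "character",
    ids = "character",
    observed = "numeric",
    responseType = "character",
    failures = "character"
  )
)

setValidity("PredictionStore", function(object) {
  msg <- character()
  n <- length(object@observed)
  bad <- vapply(object@entries, function(v) length(v) != n || anyNA(v), logical(1))
  if (any(bad))
    msg <- c(msg, "every entry must hold one non-missing prediction per observation")
  if (length(msg)) msg else TRUE
})

#' PerformanceTable: one measure value per (split, D-M combination)
#'
#' @slot values numeric matrix, splits as rows, descriptor-set/method
#'   combinations as columns (named \code{"<set>_<method>"}).
#' @slot measure measure name.
#' @slot orientation \code{"maximize"} or \code{"minimize"}.
#' @slot m tests count used by initial enhancement (NA otherwise).
#' @slot threshold classification threshold used by confusion-based measures
#'   (NA otherwise).
#' @export
setClass("PerformanceTable",
  representation(
    values = "matrix",
    measure = "character",
    orientation = "character",
    m = "numeric",
    threshold = "numeric"
  )
)

setValidity("PerformanceTable", function(object) {
  msg <- character()
  if (!is.numeric(object@values)) msg <- c(msg, "values must be numeric")
  if (is.null(colnames(object@values)))
    msg <- c(msg, "combination columns must be named")
  if (!object@orientation %in% c("maximize", "minimize"))
    msg <- c(msg, "orientation must be 'maximize' or 'minimize'")
  if (length(msg)) msg else TRUE
})

#' AnovaResult: balanced two-way additive decomposition
#'
#' Decomposition of a complete splits-by-combinations performance table under
#' the blocked model Y_ij = mu + alpha_i + beta_j + eps_ij.
#'
#' @slot grandMean grand mean.
#' @slot splitEffects,comboEffects estimated fixed effects (sum to zero).
#' @slot ss named numeric: split, combo, error, total sums of squares.
#' @slot df named numeric degrees of freedom.
#' @slot ms named numeric mean squares.
#' @slot fstat,pvalue named numeric F statistics and p-values for the two
#'   main effects.
#' @export
setClass("AnovaResult",
  representation(
    grandMean = "numeric",
    splitEffects = "numeric",
    comboEffects = "numeric",
    ss = "numeric",
    df = "numeric",
    ms = "numeric",
    fstat = "numeric",
    pvalue = "numeric"
  )
)

setValidity("AnovaResult", function(object) {
  msg <- character()
  need <- c("split", "combo", "error", "total")
  if (!all(need %in% names(object@ss))) msg <- c(msg, "ss must name split/combo/error/total")
  if (any(object@ss < -1e-8)) msg <- c(msg, "sums of squares must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' ComparisonResult: Tukey-Kramer pairwise comparisons
#'
#' @slot ordering combination names ordered best to worst by mean measure
#'   (orientation-aware).
#' @slot means named mean measure per combination.
#' @slot pairs data.frame with one row per unordered pair: \code{combo_a},
#'   \code{combo_b}, \code{mean_a}, \code{mean_b}, \code{diff}, \code{se},
#'   \code{q}, \code{p_adjusted}, \code{category}.
#' @slot bands the two significance thresholds separating the categories.
#' @slot measure,orientation carried from the performance table.
#' @export
setClass("ComparisonResult",
  representation(
    ordering = "character",
    means = "numeric",
    pairs = "data.frame",
    bands = "numeric",
    measure = "character",
    orientation = "character"
  )
)

setValidity("ComparisonResult", function(object) {
  msg <- character()
  cc <- length(object@ordering)
  if (nrow(object@pairs) != cc * (cc - 1L) / 2L)
    msg <- c(msg, "pair count must be c(c-1)/2")
  p <- object@pairs$p_adjusted
  if (any(p < 0 | p > 1, na.rm = TRUE)) msg <- c(msg, "adjusted p-values must lie in [0,1]")
  if (length(object@bands) != 2L || is.unsorted(object@bands))
    msg <- c(msg, "bands must be two increasing thresholds")
  if (length(msg)) msg else TRUE
})

#' ControlChartResult: Hotelling T-squared applicability domain
#'
#' @slot t2 T-squared statistic per external observation.
#' @slot ucl upper control limit.
#' @slot alpha significance level used for the UCL.
#' @slot outliers indices of external observations with t2 > ucl.
#' @slot center training mean vector.
#' @slot covariance training sample covariance (divisor n-1).
#' @slot ntrain training-set size.
#' @export
setClass("ControlChartResult",
  representation(
    t2 = "numeric",
    ucl = "numeric",
    alpha = "numeric",
    outliers = "integer",
    center = "numeric",
    covariance = "matrix",
    ntrain = "integer"
  )
)

setValidity("ControlChartResult", function(object) {
  msg <- character()
  if (any(object@t2 < -1e-10)) msg <- c(msg, "T2 statistics must be nonnegative")
  expected <- which(object@t2 > object@ucl)
  if (!identical(as.integer(expected), object@outliers))
    msg <- c(msg, "outliers must be exactly the positions with t2 > ucl")
  if (length(msg)) msg else TRUE
})
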