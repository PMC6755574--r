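# Performance measures on pooled out-of-fold predictions, and assembly of
# the splits x combinations performance table that feeds the blocked ANOVA.

.measureTable <- data.frame(
  name = c("error_rate", "sens", "spec", "ppv", "f1", "auc", "ie",
           "rmse", "r2", "spearman"),
  type = c(rep("binary", 7), rep("continuous", 3)),
  orientation = c("minimize", rep("maximize", 6),
                  "minimize", "maximize", "maximize"),
  stringsAsFactors = FALSE
)

#' List available performance measures
#'
#' @param responseType optionally restrict to measures valid for a response
#'   type.
#' @return data.frame of measure names, the response type they apply to, and
#'   their orientation (whether larger or smaller values are better).
#' @export
listMeasures <- function(responseType = NULL) {
  if (is.null(responseType)) return(.measureTable)
  .measureTable[.measureTable$type == responseType, ]
}

#' Threshold continuous scores into 0/1 calls
#'
#' @param scores numeric scores (probabilities or unbounded reals).
#' @param threshold cut point; a score >= threshold is called 1.
#' @return integer 0/1 vector.
#' @export
thresholdScores <- function(scores, threshold) {
  as.integer(scores >= threshold)
}

#' Confusion counts for binary predictions
#'
#' @param y observed 0/1 vector.
#' @param yhat predicted 0/1 vector of the same length.
#' @return named list with TP, FP, TN, FN.
#' @export
confusionCounts <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("'y' and 'yhat' lengths differ")
  list(TP = sum(y == 1 & yhat == 1), FP = sum(y == 0 & yhat == 1),
       TN = sum(y == 0 & yhat == 0), FN = sum(y == 1 & yhat == 0))
}

#' Confusion-based binary measures
#'
#' Error rate, sensitivity, specificity, positive predictive value
#' (precision) and F1 (the harmonic mean of sensitivity and PPV).  A 0/0
#' ratio yields \code{NaN}, the undefined marker propagated (and eventually
#' dropped, with a warning) by \code{\link{buildPerformanceTable}}.
#'
#' @param counts a list from \code{\link{confusionCounts}}.
#' @return named list of the five measures.
#' @export
binaryMeasures <- function(counts) {
  n <- counts$TP + counts$FP + counts$TN + counts$FN
  ratio <- function(num, den) if (den == 0) NaN else num / den
  sens <- ratio(counts$TP, counts$TP + counts$FN)
  ppv <- ratio(counts$TP, counts$TP + counts$FP)
  f1 <- if (is.nan(sens) || is.nan(ppv) || (sens + ppv) == 0) NaN
        else 2 * sens * ppv / (sens + ppv)
  list(
    error_rate = ratio(counts$FP + counts$FN, n),
    sens = sens,
    spec = ratio(counts$TN, counts$TN + counts$FP),
    ppv = ppv,
    f1 = f1
  )
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability that a positive outscores a
#' negative, with ties counted one half.
#'
#' @param y observed 0/1 vector with at least one of each class.
#' @param scores predicted scores (any real scale).
#' @return AUC in [0, 1].
#' @export
aucScore <- function(y, scores) {
  if (length(y) != length(scores)) stop("'y' and 'scores' lengths differ")
  P <- sum(y == 1); N <- sum(y == 0)
  if (P == 0 || N == 0) stop("AUC needs at least one positive and one negative")
  r <- rank(scores)
  (sum(r[y == 1]) - P * (P + 1) / 2) / (P * N)
}

# Stable top-m selection: decreasing score, original row order breaking ties.
topMOrder <- function(scores) order(-scores, seq_along(scores))

#' Initial enhancement (hit enrichment factor) at m tests
#'
#' The hit rate among the m highest-scored observations divided by the
#' proportion of positives in the whole data set: IE = (h/m) / (p/n).  A
#' model no better than random has expected IE 1; a perfect ranking assessed
#' at m = p gives n/p.  Ties in the ranking are broken by original row order
#' (stable sort).
#'
#' @param y observed 0/1 vector with at least one positive.
#' @param scores predicted scores.
#' @param m number of tests, 1 <= m <= n (default 300, capped by the caller).
#' @return the enrichment factor.
#' @export
initialEnhancement <- function(y, scores, m = 300) {
  n <- length(y)
  if (m > n) stop("'m' must not exceed the number of observations")
  if (m < 1) stop("'m' must be at least 1")
  p <- sum(y == 1)
  if (p < 1) stop("initial enhancement needs at least one positive")
  h <- sum(y[topMOrder(scores)[seq_len(m)]] == 1)
  (h / m) / (p / n)
}

#' Continuous-response measures
#'
#' @param y observed response (length >= 3).
#' @param yhat predictions.
#' @return named list of rmse, r2 (1 - SSres/SStot) and spearman (Pearson
#'   correlation of midranks); r2/spearman are \code{NaN} when y or the
#'   predictions are degenerate.
#' @export
continuousMeasures <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("'y' and 'yhat' lengths differ")
  if (length(y) < 3) stop("at least 3 observations are required")
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot == 0) NaN else 1 - sum((y - yhat)^2) / sstot
  sp <- if (sstot == 0 || stats::var(yhat) == 0) NaN
        else stats::cor(rank(y), rank(yhat))
  list(rmse = sqrt(mean((y - yhat)^2)), r2 = r2, spearman = sp)
}

measureValue <- function(measure, y, scores, m, threshold) {
  switch(measure,
    auc = aucScore(y, scores),
    ie = initialEnhancement(y, scores, m),
    rmse = continuousMeasures(y, scores)$rmse,
    r2 = continuousMeasures(y, scores)$r2,
    spearman = continuousMeasures(y, scores)$spearman,
    # confusion-based
    binaryMeasures(confusionCounts(y, thresholdScores(scores, threshold)))[[measure]]
  )
}

#' Build the splits-by-combinations performance table
#'
#' Computes one measure value per (split, descriptor-set/method combination)
#' on that split's pooled n out-of-fold predictions.  Columns with an
#' undefined value (0/0 confusion ratio) in any split, or combinations that
#' failed to run, are dropped whole with a warning so the remaining table is
#' complete and balanced.
#'
#' @param store a \linkS4class{PredictionStore}.
#' @param measure one of \code{\link{listMeasures}}'s names; binary measures
#'   require a binary response and vice versa.
#' @param m tests count for \code{"ie"}; default \code{min(300, n)}.
#' @param threshold classification threshold for confusion-based measures
#'   (default 0.5, applied identically to probabilities and unbounded
#'   continuous-model scores).
#' @return a \linkS4class{PerformanceTable}.
#' @export
buildPerformanceTable <- function(store, measure, m = NULL, threshold = 0.5) {
  stopifnot(is(store, "PredictionStore"))
  row <- .measureTable[.measureTable$name == measure, ]
  if (!nrow(row))
    stop("unknown measure '", measure, "'; valid measures: ",
         paste(.measureTable$name, collapse = ", "))
  if (row$type != store@responseType)
    stop("measure '", measure, "' requires a ", row$type,
         " response; valid measures here: ",
         paste(listMeasures(store@responseType)$name, collapse = ", "))
  if (!length(store@entries)) stop("the prediction store is empty")
  y <- store@observed
  if (measure == "ie") {
    if (is.null(m)) m <- min(300L, length(y))
  } else m <- NA_real_

  keys <- names(store@entries)
  parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  splits <- sort(unique(as.integer(parts[, 1])))
  combos <- unique(paste(parts[, 2], parts[, 3], sep = "_"))
  vals <- matrix(NA_real_, length(splits), length(combos),
                 dimnames = list(paste0("split", splits), combos))
  for (i in seq_along(keys)) {
    cn <- paste(parts[i, 2], parts[i, 3], sep = "_")
    vals[match(as.integer(parts[i, 1]), splits), cn] <-
      measureValue(measure, y, store@entries[[i]], m, threshold)
  }
  bad <- colnames(vals)[apply(vals, 2, function(v) any(is.na(v) | is.nan(v)))]
  if (length(bad)) {
    warning("dropping incomplete/undefined combination(s): ",
            paste(bad, collapse = ", "), call. = FALSE)
    vals <- vals[, setdiff(colnames(vals), bad), drop = FALSE]
  }
  if (!ncol(vals)) stop("no combination produced a complete set of values")
  new("PerformanceTable", values = vals, measure = measure,
      orientation = row$orientation, m = as.numeric(m),
      threshold = if (row$type == "binary" && !measure %in% c("auc", "ie"))
        threshold else NA_real_)
}

#' Construct a PerformanceTable from a plain matrix
#'
#' Useful for assembling a table outside \code{\link{buildPerformanceTable}}
#' (e.g. from a CSV or a simulation).
#'
#' @param values numeric matrix, splits as rows, combinations as named
#'   columns.
#' @param measure measure label (default \code{"measure"}).
#' @param orientation \code{"maximize"} (default) or \code{"minimize"}.
#' @return a \linkS4class{PerformanceTable}.
#' @export
performanceTable <- function(values, measure = "measure",
                             orientation = c("maximize", "minimize")) {
  orientation <- match.arg(orientation)
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("combo", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- paste0("split", seq_len(nrow(values)))
  new("PerformanceTable", values = values, measure = measure,
      orientation = orientation, m = NA_real_, threshold = NA_real_)
}
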