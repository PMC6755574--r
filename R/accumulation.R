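# Accumulation (hit-enrichment) curves: cumulative response over observations
# ordered by decreasing predicted score, with ideal and expected-random
# reference curves.  The binary positives-counting curve is the special case
# of the continuous definition on a 0/1 response.

#' Default maximum number of tests for accumulation curves
#'
#' floor(min(300, n/4)): prioritizes finding actives within a relatively
#' small number of tests.
#'
#' @param n observation count (>= 4).
#' @return integer test budget.
#' @examples defaultMaxSelect(500)  # 125
#' @export
defaultMaxSelect <- function(n) {
  if (n < 4) stop("'n' must be at least 4")
  as.integer(floor(min(300, n / 4)))
}

newCurve <- function(accumulated, kind, label = "") {
  structure(
    list(tests = seq_along(accumulated), accumulated = accumulated,
         kind = kind, label = label),
    class = "AccumulationCurve"
  )
}

#' Accumulation curve of a scored ranking
#'
#' Observations are ordered by decreasing predicted score (ties broken by
#' original row order); entry m of the curve is the sum of the response over
#' the first m tests.
#'
#' @param y observed response (binary 0/1 or continuous).
#' @param scores predicted scores.
#' @param maxSelect number of tests to accumulate, 1 <= maxSelect <= n
#'   (default \code{\link{defaultMaxSelect}}).
#' @param label optional curve label.
#' @return an \code{AccumulationCurve}: list with \code{tests},
#'   \code{accumulated}, \code{kind = "model"}.
#' @export
accumulationCurve <- function(y, scores, maxSelect = defaultMaxSelect(length(y)),
                              label = "") {
  if (length(y) != length(scores)) stop("'y' and 'scores' lengths differ")
  if (maxSelect < 1 || maxSelect > length(y))
    stop("'maxSelect' must lie in 1..n")
  acc <- cumsum(y[topMOrder(scores)])[seq_len(maxSelect)]
  newCurve(acc, "model", label)
}

#' Ideal accumulation curve
#'
#' The curve of a model that ranks perfectly: the response sorted in
#' decreasing order, accumulated.  For a binary response this equals
#' min(m, p) at m tests.
#'
#' @inheritParams accumulationCurve
#' @return an \code{AccumulationCurve} with \code{kind = "ideal"}.
#' @export
idealCurve <- function(y, maxSelect = defaultMaxSelect(length(y))) {
  if (maxSelect < 1 || maxSelect > length(y))
    stop("'maxSelect' must lie in 1..n")
  newCurve(cumsum(sort(y, decreasing = TRUE))[seq_len(maxSelect)], "ideal",
           "ideal")
}

#' Random-order accumulation curve
#'
#' The expected accumulation if the testing order were decided at random:
#' the straight line m * sum(y) / n (slope p/n for a binary response).
#'
#' @inheritParams accumulationCurve
#' @return an \code{AccumulationCurve} with \code{kind = "random"}.
#' @export
randomCurve <- function(y, maxSelect = defaultMaxSelect(length(y))) {
  if (maxSelect < 1 || maxSelect > length(y))
    stop("'maxSelect' must lie in 1..n")
  newCurve(seq_len(maxSelect) * sum(y) / length(y), "random", "random")
}

#' Group accumulation curves into the "descriptors"/"methods" plot series
#'
#' In the \code{"descriptors"} series there is one plot group per (split,
#' descriptor set); the curves of every method are grouped together for
#' comparison.  In the \code{"methods"} series there is one group per (split,
#' method) holding one curve per descriptor set.  Every group also carries
#' the ideal and random reference curves.
#'
#' @param store a \linkS4class{PredictionStore}.
#' @param series \code{"descriptors"}, \code{"methods"} or \code{"both"}.
#' @param splits optional subset of split indices.
#' @param meths optional subset of method names.
#' @param maxSelect tests budget (default \code{\link{defaultMaxSelect}}).
#' @return named list of plot groups; each group is a list of
#'   \code{AccumulationCurve}s.
#' @export
curveSeries <- function(store, series = c("descriptors", "methods", "both"),
                        splits = NULL, meths = NULL,
                        maxSelect = defaultMaxSelect(nObs(store))) {
  series <- match.arg(series)
  stopifnot(is(store, "PredictionStore"))
  keys <- names(store@entries)
  if (!length(keys)) stop("the prediction store is empty")
  parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  info <- data.frame(split = as.integer(parts[, 1]), set = parts[, 2],
                     method = parts[, 3], key = keys, stringsAsFactors = FALSE)
  if (!is.null(splits)) info <- info[info$split %in% splits, ]
  if (!is.null(meths)) info <- info[info$method %in% meths, ]
  if (!nrow(info)) stop("no stored combination matches the requested subset")
  y <- store@observed
  ideal <- idealCurve(y, maxSelect)
  rand <- randomCurve(y, maxSelect)

  buildGroups <- function(byCols, curveLabelCol) {
    groups <- split(info, info[byCols], drop = TRUE, sep = " / ")
    lapply(groups, function(g) {
      curves <- lapply(seq_len(nrow(g)), function(i)
        accumulationCurve(y, store@entries[[g$key[i]]], maxSelect,
                          label = g[[curveLabelCol]][i]))
      names(curves) <- g[[curveLabelCol]]
      c(curves, list(ideal = ideal, random = rand))
    })
  }

  out <- list()
  if (series %in% c("descriptors", "both"))
    out <- c(out, buildGroups(c("split", "set"), "method"))
  if (series %in% c("methods", "both"))
    out <- c(out, buildGroups(c("split", "method"), "set"))
  out
}

#' Export curve groups as a long data.frame
#'
#' @param groups output of \code{\link{curveSeries}}.
#' @return data.frame with columns group, curve, kind, tests, accumulated.
#' @export
curveCoordinates <- function(groups) {
  rows <- lapply(names(groups), function(gn) {
    g <- groups[[gn]]
    do.call(rbind, lapply(names(g), function(cn) {
      cv <- g[[cn]]
      data.frame(group = gn, curve = cn, kind = cv$kind, tests = cv$tests,
                 accumulated = cv$accumulated, stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}
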