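# CART recursive partitioning and a random forest built on it.
#
# Splits minimize the sum of squared errors of the child means; on a 0/1
# response this criterion is equivalent to the Gini impurity, so the same
# grower serves classification (leaf value = proportion of actives, i.e. a
# probability) and regression (leaf value = mean response).  "Tree" and
# "RPart" are two configurations of this grower: Tree grows deep with a tiny
# complexity penalty, RPart uses the conventional minsplit-20 / cp-0.01
# pruning-by-construction settings.

# Best SSE-decrease split of one column.  Returns NULL or list(cut, gain).
cartBestSplitCol <- function(x, y, minbucket) {
  n <- length(y)
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  cs <- cumsum(ys)
  total <- cs[n]
  i <- seq_len(n - 1L)
  valid <- (xs[i] < xs[i + 1L]) & (i >= minbucket) & ((n - i) >= minbucket)
  if (!any(valid)) return(NULL)
  i <- i[valid]
  # SSE decrease = n-weighted between-group variance of the two child means
  gain <- cs[i]^2 / i + (total - cs[i])^2 / (n - i) - total^2 / n
  bi <- which.max(gain)
  list(cut = (xs[i[bi]] + xs[i[bi] + 1L]) / 2, var = NA_integer_,
       gain = gain[bi], col = NA_integer_, at = i[bi])
}

cartGrow <- function(X, y, rows, depth, minsplit, maxdepth, minGain, mtry) {
  yv <- y[rows]
  node <- list(value = mean(yv))
  if (length(rows) < minsplit || depth >= maxdepth ||
      stats::var(yv) < 1e-12 || !is.finite(minGain))
    return(node)
  p <- ncol(X)
  cand <- if (is.null(mtry) || mtry >= p) seq_len(p)
          else sample.int(p, mtry)
  minbucket <- max(1L, minsplit %/% 3L)
  best <- NULL
  for (j in cand) {
    sp <- cartBestSplitCol(X[rows, j], yv, minbucket)
    if (!is.null(sp) && (is.null(best) || sp$gain > best$gain)) {
      sp$col <- j
      best <- sp
    }
  }
  if (is.null(best) || best$gain < minGain) return(node)
  goesLeft <- X[rows, best$col] <= best$cut
  left <- rows[goesLeft]
  right <- rows[!goesLeft]
  node$col <- best$col
  node$cut <- best$cut
  node$left <- cartGrow(X, y, left, depth + 1L, minsplit, maxdepth, minGain, mtry)
  node$right <- cartGrow(X, y, right, depth + 1L, minsplit, maxdepth, minGain, mtry)
  node
}

cartPredictOne <- function(node, x) {
  while (!is.null(node$col)) {
    node <- if (x[node$col] <= node$cut) node$left else node$right
  }
  node$value
}

cartPredict <- function(tree, X) {
  apply(X, 1L, function(r) cartPredictOne(tree, r))
}

# cp is a cost-complexity threshold relative to the root deviance, as in the
# conventional recursive-partitioning parameterization: a split must reduce
# the total SSE by at least cp * root SSE.
cartScore <- function(X, y, testX, minsplit, maxdepth, cp) {
  rootDev <- sum((y - mean(y))^2)
  minGain <- cp * rootDev
  tree <- cartGrow(X, y, seq_along(y), 0L, minsplit, maxdepth, minGain,
                   mtry = NULL)
  cartPredict(tree, testX)
}

# Random forest: bootstrap-resampled CART trees with mtry features sampled
# at every node; predictions are the mean of the tree predictions (for a
# binary response each tree yields a leaf proportion, so the aggregate is a
# probability in [0, 1]).
rfScore <- function(X, y, testX, ntree, mtry, minsplit, maxdepth, binary) {
  n <- nrow(X); p <- ncol(X)
  if (is.null(mtry) || is.na(mtry))
    mtry <- if (binary) max(1L, floor(sqrt(p))) else max(1L, floor(p / 3))
  mtry <- min(p, max(1L, as.integer(mtry)))
  acc <- numeric(nrow(testX))
  for (b in seq_len(ntree)) {
    idx <- sample.int(n, n, replace = TRUE)
    Xb <- X[idx, , drop = FALSE]
    yb <- y[idx]
    tree <- cartGrow(Xb, yb, seq_len(n), 0L, minsplit, maxdepth,
                     minGain = 0, mtry = mtry)
    acc <- acc + cartPredict(tree, testX)
  }
  acc / ntree
}
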