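# Applicability domain via a phase-II Hotelling T2 control chart: external
# observations far from the training descriptor distribution (in Mahalanobis
# terms) are extrapolations and flagged as outside the domain.

#' Hotelling T2 statistics for external observations
#'
#' T2(x) = (x - xbar)' S^{-1} (x - xbar), the squared Mahalanobis distance of
#' each external row from the training mean xbar under the training sample
#' covariance S (divisor n-1).  Being covariance-adjusted, T2 flags
#' correlation-structure violators that Euclidean distance misses, and is
#' invariant under invertible affine maps of the descriptor space.
#'
#' @param trainX n x p training descriptor matrix with n > p.
#' @param newX m x p matrix of external observations (same columns).
#' @param shrinkage optional ridge shrinkage in [0, 1) applied to the
#'   covariance, \code{(1 - shrinkage) * S + shrinkage * diag(diag(S))};
#'   default 0 (off).
#' @return numeric vector of m nonnegative T2 values.
#' @export
hotellingT2 <- function(trainX, newX, shrinkage = 0) {
  trainX <- as.matrix(trainX); newX <- as.matrix(newX)
  if (ncol(trainX) != ncol(newX)) stop("column counts differ")
  n <- nrow(trainX); p <- ncol(trainX)
  if (n <= p && shrinkage == 0)
    stop("training size must exceed the descriptor count for an invertible ",
         "covariance; reduce dimension or enable shrinkage")
  S <- stats::cov(trainX)
  if (shrinkage > 0)
    S <- (1 - shrinkage) * S + shrinkage * diag(diag(S), p)
  ok <- tryCatch({ solve(S); TRUE }, error = function(e) FALSE)
  if (!ok)
    stop("singular training covariance; reduce the descriptor dimension ",
         "(e.g. drop collinear columns) or enable shrinkage")
  stats::mahalanobis(newX, colMeans(trainX), S)
}

#' Upper control limit for T2 of future individual observations
#'
#' The phase-II limit for new individuals: UCL = p (n+1) (n-1) /
#' (n (n-p)) * F_{1-alpha}(p, n-p).  Monotone decreasing in alpha.
#'
#' @param n training-set size.
#' @param p descriptor count (n > p).
#' @param alpha significance level in (0, 1); default 0.05.
#' @return the control limit.
#' @export
hotellingUCL <- function(n, p, alpha = 0.05) {
  if (n <= p) stop("'n' must exceed 'p'")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")
  p * (n + 1) * (n - 1) / (n * (n - p)) *
    stats::qf(1 - alpha, p, n - p)
}

#' Hotelling T2 control chart for applicability-domain assessment
#'
#' Computes \code{\link{hotellingT2}} for every external observation and the
#' \code{\link{hotellingUCL}} at level alpha; observations beyond the limit
#' are outside the applicability domain and their predictions should be
#' treated as extrapolations.
#'
#' @inheritParams hotellingT2
#' @param alpha significance level for the control limit.
#' @return a \linkS4class{ControlChartResult}.
#' @export
controlChart <- function(trainX, newX, alpha = 0.05, shrinkage = 0) {
  trainX <- as.matrix(trainX)
  t2 <- hotellingT2(trainX, newX, shrinkage = shrinkage)
  ucl <- hotellingUCL(nrow(trainX), ncol(trainX), alpha)
  new("ControlChartResult", t2 = t2, ucl = ucl, alpha = alpha,
      outliers = which(t2 > ucl), center = colMeans(trainX),
      covariance = stats::cov(trainX), ntrain = nrow(trainX))
}
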