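# Synthetic data generators.  The default binary fixture mirrors the shape of
# the packaged cytotoxicity-assay subset this workflow is usually
# demonstrated on: 500 compounds of which 50 are active, one set of 24
# continuous descriptors and one of 147 binary (presence/absence) descriptors.
# Signal is injected as a mean shift of informative continuous descriptors and
# a success-probability shift of informative binary descriptors for actives,
# so effect = 0 gives an exact null.

#' Synthetic binary-response QSAR-like dataset
#'
#' Generates a \linkS4class{ModelingDataset} with two descriptor sets:
#' \code{"ContinuousSet"} (standard-normal columns) and \code{"BinarySet"}
#' (Bernoulli(0.2) columns).  For the active compounds, an
#' \code{informativeFraction} share of the columns of each set carries
#' signal: continuous informative columns are shifted by \code{effect},
#' binary informative columns have their success probability raised by
#' \code{0.15 * effect} (capped at 0.95).  Bit-reproducible given the seed.
#'
#' @param n observations (default 500).
#' @param nActive positives, 0 < nActive < n (default 50).
#' @param nContinuousDesc,nBinaryDesc set widths (defaults 24 and 147).
#' @param effect nonnegative signal strength (default 1; 0 = exact null).
#' @param informativeFraction share of columns carrying signal (default 0.25).
#' @param seed integer seed (default 1).
#' @return a \linkS4class{ModelingDataset} with exactly \code{nActive} ones.
#' @export
makeBinaryDataset <- function(n = 500L, nActive = 50L,
                              nContinuousDesc = 24L, nBinaryDesc = 147L,
                              effect = 1, informativeFraction = 0.25,
                              seed = 1L) {
  if (nActive <= 0 || nActive >= n) stop("need 0 < nActive < n")
  if (effect < 0) stop("'effect' must be nonnegative")
  if (nContinuousDesc < 1 || nBinaryDesc < 1) stop("set widths must be >= 1")
  withSeed(seed, {
    y <- sample(rep(c(1, 0), c(nActive, n - nActive)))
    act <- y == 1

    nInfC <- max(1L, round(informativeFraction * nContinuousDesc))
    Xc <- matrix(stats::rnorm(n * nContinuousDesc), n, nContinuousDesc)
    Xc[act, seq_len(nInfC)] <- Xc[act, seq_len(nInfC)] + effect
    colnames(Xc) <- paste0("cont", seq_len(nContinuousDesc))

    nInfB <- max(1L, round(informativeFraction * nBinaryDesc))
    p0 <- 0.2
    pAct <- min(0.95, p0 + 0.15 * effect)
    prob <- matrix(p0, n, nBinaryDesc)
    prob[act, seq_len(nInfB)] <- pAct
    Xb <- matrix(as.numeric(stats::runif(n * nBinaryDesc) < prob),
                 n, nBinaryDesc)
    colnames(Xb) <- paste0("bin", seq_len(nBinaryDesc))

    makeModelingDataset(list(ContinuousSet = Xc, BinarySet = Xb), y,
                        responseType = "binary")
  })
}

#' Synthetic continuous-response dataset
#'
#' y = effect * (sum of the informative standard-normal descriptors) +
#' N(0, noiseSd^2) noise.  The default size mirrors the 277-compound
#' boiling-point example commonly used for the continuous pathway.
#'
#' @param n observations (default 277, >= 10).
#' @param nDesc descriptor count (default 10), in one set named
#'   \code{"descriptors"}.
#' @param effect coefficient of the informative descriptors (default 1).
#' @param noiseSd Gaussian noise standard deviation (default 1).
#' @param informativeFraction share of informative columns (default 0.3).
#' @param seed integer seed (default 1).
#' @return a \linkS4class{ModelingDataset} with a continuous response.
#' @export
makeContinuousDataset <- function(n = 277L, nDesc = 10L, effect = 1,
                                  noiseSd = 1, informativeFraction = 0.3,
                                  seed = 1L) {
  if (n < 10) stop("'n' must be at least 10")
  if (nDesc < 1) stop("'nDesc' must be >= 1")
  withSeed(seed, {
    X <- matrix(stats::rnorm(n * nDesc), n, nDesc)
    colnames(X) <- paste0("d", seq_len(nDesc))
    nInf <- max(1L, round(informativeFraction * nDesc))
    y <- effect * rowSums(X[, seq_len(nInf), drop = FALSE]) +
      stats::rnorm(n, sd = noiseSd)
    makeModelingDataset(X, y, responseType = "continuous")
  })
}

#' Synthetic performance table for exercising the blocked ANOVA
#'
#' Y_ij = mu + alpha_i + delta * 1[j = elevated] + N(0, sigma^2), with fixed
#' split effects alpha_i = 0.25 * (i - (s+1)/2) (sum-to-zero).  sigma = 0
#' with no elevation makes the additive model exact (SS_error = 0).
#'
#' @param s splits (>= 2).
#' @param c combinations (>= 2).
#' @param sigma noise standard deviation (default 1).
#' @param elevated optional list(index =, delta =) raising one combination's
#'   mean by delta.
#' @param mu grand mean (default 1).
#' @param orientation orientation of the fictitious measure (default
#'   \code{"maximize"}, so an elevated combination is best).
#' @param seed integer seed (default 1).
#' @return a \linkS4class{PerformanceTable}.
#' @export
makePerformanceTable <- function(s, c, sigma = 1, elevated = NULL, mu = 1,
                                 orientation = "maximize", seed = 1L) {
  if (s < 2 || c < 2) stop("need s >= 2 and c >= 2")
  withSeed(seed, {
    alpha <- 0.25 * (seq_len(s) - (s + 1) / 2)
    Y <- matrix(mu + alpha, s, c) +
      matrix(stats::rnorm(s * c, sd = sigma), s, c)
    if (!is.null(elevated))
      Y[, elevated$index] <- Y[, elevated$index] + elevated$delta
    colnames(Y) <- paste0("combo", seq_len(c))
    rownames(Y) <- paste0("split", seq_len(s))
    performanceTable(Y, measure = "synthetic", orientation = orientation)
  })
}
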