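# The inferential core: blocked two-way ANOVA on the performance table,
# Tukey-Kramer multiplicity-adjusted pairwise comparisons of the D-M
# combinations, and the multiple-comparisons-similarity (MCS) matrix.

#' Number of unordered pairwise comparisons
#'
#' @param c number of D-M combinations (>= 2).
#' @return c(c-1)/2; e.g. 18 combinations yield 153 comparisons.
#' @export
nPairs <- function(c) {
  if (c < 2) stop("at least 2 combinations are required")
  c * (c - 1) / 2
}

#' Blocked two-way ANOVA of a performance table
#'
#' Fits the additive fixed-effects model Y_ij = mu + alpha_i + beta_j +
#' eps_ij, with the cross-validation split i as the blocking factor and the
#' D-M combination j as the factor of interest (one observation per cell, no
#' interaction).  The balanced closed form is used: SS_split =
#' c * sum_i (rowmean_i - grand)^2, SS_combo = s * sum_j (colmean_j - grand)^2,
#' SS_error by subtraction; F tests on (s-1, (s-1)(c-1)) and (c-1, (s-1)(c-1))
#' degrees of freedom.
#'
#' @param table a complete \linkS4class{PerformanceTable} with at least 2
#'   splits and 2 combinations.
#' @return an \linkS4class{AnovaResult}.
#' @export
blockedAnova <- function(table) {
  stopifnot(is(table, "PerformanceTable"))
  Y <- table@values
  if (anyNA(Y))
    stop("the performance table is incomplete; drop incomplete columns first")
  s <- nrow(Y); cc <- ncol(Y)
  if (s < 2 || cc < 2)
    stop("the blocked ANOVA needs at least 2 splits and 2 combinations ",
         "(error df = (s-1)(c-1) must be >= 1)")
  grand <- mean(Y)
  rm <- rowMeans(Y); cm <- colMeans(Y)
  ssSplit <- cc * sum((rm - grand)^2)
  ssCombo <- s * sum((cm - grand)^2)
  ssTotal <- sum((Y - grand)^2)
  ssError <- max(0, ssTotal - ssSplit - ssCombo)
  df <- c(split = s - 1, combo = cc - 1, error = (s - 1) * (cc - 1),
          total = s * cc - 1)
  ms <- c(split = ssSplit / df["split"], combo = ssCombo / df["combo"],
          error = ssError / df["error"])
  names(ms) <- c("split", "combo", "error")
  fs <- c(split = unname(ms["split"] / ms["error"]),
          combo = unname(ms["combo"] / ms["error"]))
  pv <- c(split = stats::pf(fs["split"], df["split"], df["error"],
                            lower.tail = FALSE),
          combo = stats::pf(fs["combo"], df["combo"], df["error"],
                            lower.tail = FALSE))
  names(pv) <- c("split", "combo")
  new("AnovaResult", grandMean = grand,
      splitEffects = rm - grand, comboEffects = cm - grand,
      ss = c(split = ssSplit, combo = ssCombo, error = ssError,
             total = ssTotal),
      df = df, ms = ms, fstat = fs, pvalue = pv)
}

#' Tukey-Kramer pairwise comparisons of D-M combinations
#'
#' For every unordered pair of combinations, the difference of combination
#' means d, its standard error sqrt(MS_error / s) on the studentized-range
#' scale, the statistic q = |d| / SE, and the multiplicity-adjusted p-value
#' P(Q_{c, df_error} >= q) from the studentized range distribution.  Pairs are
#' binned into the significance categories \code{"p<=0.01"},
#' \code{"0.01<p<=0.05"} and \code{"p>0.05"} (band edges configurable).
#'
#' @param table the \linkS4class{PerformanceTable} the ANOVA was computed on.
#' @param anova optional \linkS4class{AnovaResult}; recomputed when omitted.
#' @param bands two increasing significance thresholds (default 0.01, 0.05).
#' @return a \linkS4class{ComparisonResult}; combinations are ordered best to
#'   worst by mean measure, respecting the measure's orientation.
#' @export
tukeyKramer <- function(table, anova = NULL, bands = c(0.01, 0.05)) {
  stopifnot(is(table, "PerformanceTable"))
  if (is.null(anova)) anova <- blockedAnova(table)
  Y <- table@values
  s <- nrow(Y); cc <- ncol(Y)
  means <- colMeans(Y)
  dfe <- anova@df[["error"]]
  mse <- anova@ms[["error"]]
  se <- sqrt(mse / s)
  degenerate <- mse <= 0
  if (degenerate)
    warning("MS_error is zero: nonzero differences get p = 0, ",
            "zero differences p = 1", call. = FALSE)

  ord <- order(means, decreasing = table@orientation == "maximize")
  ordering <- colnames(Y)[ord]

  idx <- utils::combn(cc, 2)
  a <- idx[1, ]; b <- idx[2, ]
  d <- means[a] - means[b]
  if (degenerate) {
    q <- ifelse(d == 0, 0, Inf)
    p <- ifelse(d == 0, 1, 0)
  } else {
    q <- abs(d) / se
    # c = 2 has the exact closed form P(Q >= q) = P(|t_df| >= q/sqrt(2)),
    # more accurate than the ptukey approximation
    p <- if (cc == 2L) 2 * stats::pt(q / sqrt(2), dfe, lower.tail = FALSE)
         else stats::ptukey(q, nmeans = cc, df = dfe, lower.tail = FALSE)
  }
  category <- cut(p, breaks = c(-Inf, bands, Inf),
                  labels = c(sprintf("p<=%g", bands[1]),
                             sprintf("%g<p<=%g", bands[1], bands[2]),
                             sprintf("p>%g", bands[2])))
  pairs <- data.frame(
    combo_a = colnames(Y)[a], combo_b = colnames(Y)[b],
    mean_a = unname(means[a]), mean_b = unname(means[b]),
    diff = unname(d), se = if (degenerate) NA_real_ else se,
    q = unname(q), p_adjusted = unname(p),
    category = as.character(category),
    stringsAsFactors = FALSE
  )
  new("ComparisonResult", ordering = ordering, means = means, pairs = pairs,
      bands = bands, measure = table@measure, orientation = table@orientation)
}

#' MCS matrix of pairwise significance categories
#'
#' A symmetric c x c character matrix whose rows and columns are the D-M
#' combinations ordered best to worst; cell (j, j') holds the pair's
#' significance category and the diagonal is \code{"self"}.
#'
#' @param comp a \linkS4class{ComparisonResult}.
#' @return character matrix.
#' @export
mcsMatrix <- function(comp) {
  stopifnot(is(comp, "ComparisonResult"))
  combos <- comp@ordering
  m <- matrix("self", length(combos), length(combos),
              dimnames = list(combos, combos))
  pr <- comp@pairs
  for (i in seq_len(nrow(pr))) {
    m[pr$combo_a[i], pr$combo_b[i]] <- pr$category[i]
    m[pr$combo_b[i], pr$combo_a[i]] <- pr$category[i]
  }
  m
}
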