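# Shared helpers: tiny in-code fixtures for tests.

# A small PredictionStore built directly (no model fitting): `splits` splits,
# `sets` x `methods` combinations, scores drawn from a seeded RNG with signal
# added for positives.
tinyStore <- function(n = 40, nPos = 10, splits = 2, sets = c("A", "B"),
                      methods = c("m1", "m2"), seed = 42,
                      responseType = "binary") {
  set.seed(seed)
  y <- if (responseType == "binary") sample(rep(c(1, 0), c(nPos, n - nPos)))
       else rnorm(n)
  entries <- list()
  for (s in seq_len(splits))
    for (d in sets)
      for (m in methods)
        entries[[paste(s, d, m, sep = "|")]] <- rnorm(n) + 0.8 * y
  new("PredictionStore", entries = entries, splits = seq_len(splits),
      setNames = sets, methodNames = methods,
      ids = as.character(seq_len(n)), observed = as.numeric(y),
      responseType = responseType, failures = character())
}

# Write a small modeling CSV and return its path.
tinyCsv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Brute-force AUC oracle: explicit loop over all positive-negative pairs.
bruteForceAuc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}
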