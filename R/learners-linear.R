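# Linear least-squares learners: penalized regression via glmnet, and
# in-package least angle regression, principal components regression and
# SIMPLS partial least squares.  All are fit with a gaussian loss; applied to
# a 0/1 response they yield unbounded scores (never clipped here).

# Elastic-net family.  lambda = "cv" selects the penalty by an internal
# 5-fold grid on the training fold (deterministic folds: the caller seeds the
# RNG); a numeric lambda is used as-is.
glmnetScore <- function(X, y, testX, alpha, lambda) {
  # glmnet requires >= 2 columns; pad with a constant (gets coefficient 0)
  if (ncol(X) < 2L) {
    X <- cbind(X, 0)
    testX <- cbind(testX, 0)
  }
  n <- nrow(X)
  if (identical(lambda, "cv") && n >= 12L) {
    nf <- min(5L, n %/% 3L)
    foldid <- rep_len(seq_len(nf), n)[sample.int(n)]
    cvfit <- glmnet::cv.glmnet(X, y, alpha = alpha, family = "gaussian",
                               standardize = FALSE, foldid = foldid)
    as.numeric(stats::predict(cvfit, newx = testX, s = "lambda.min"))
  } else {
    fit <- glmnet::glmnet(X, y, alpha = alpha, family = "gaussian",
                          standardize = FALSE)
    s <- if (is.numeric(lambda)) lambda else stats::median(fit$lambda)
    as.numeric(stats::predict(fit, newx = testX, s = s))
  }
}

# Least angle regression path (Efron et al. forward equiangular walk) on
# centered data.  Returns the (steps+1) x p coefficient matrix, row 1 the
# null model.
larPath <- function(X, y, maxSteps) {
  n <- nrow(X); p <- ncol(X)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  yc <- y - ym
  maxSteps <- min(maxSteps, p, n - 1L)
  beta <- matrix(0, maxSteps + 1L, p)
  mu <- rep(0, n)
  active <- integer(0)
  eps <- 1e-10
  for (step in seq_len(maxSteps)) {
    c_all <- drop(crossprod(Xc, yc - mu))
    inactive <- setdiff(seq_len(p), active)
    if (!length(inactive)) break
    C <- max(abs(c_all[inactive]))
    if (C < eps) break
    jnew <- inactive[which.max(abs(c_all[inactive]))]
    active <- c(active, jnew)
    sgn <- sign(c_all[active])
    XA <- sweep(Xc[, active, drop = FALSE], 2, sgn, `*`)
    G <- crossprod(XA)
    Ginv1 <- tryCatch(solve(G, rep(1, length(active))),
                      error = function(e) NULL)
    if (is.null(Ginv1)) { active <- active[-length(active)]; break }
    AA <- 1 / sqrt(sum(Ginv1))
    w <- AA * Ginv1
    u <- drop(XA %*% w)
    if (length(active) == p) {
      gamma <- C / AA
    } else {
      a <- drop(crossprod(Xc, u))
      rest <- setdiff(seq_len(p), active)
      cand <- c((C - c_all[rest]) / (AA - a[rest]),
                (C + c_all[rest]) / (AA + a[rest]))
      cand <- cand[is.finite(cand) & cand > eps]
      gamma <- if (length(cand)) min(cand, C / AA) else C / AA
    }
    beta[step + 1L, ] <- beta[step, ]
    beta[step + 1L, active] <- beta[step + 1L, active] + gamma * sgn * w
    mu <- mu + gamma * u
    if (step >= maxSteps) break
  }
  list(beta = beta, xm = xm, ym = ym)
}

larPredict <- function(path, step, newX) {
  b <- path$beta[step + 1L, ]
  drop(sweep(newX, 2, path$xm) %*% b) + path$ym
}

# LAR with the step count chosen by internal 5-fold CV on the training fold.
larScore <- function(X, y, testX, maxSteps) {
  n <- nrow(X)
  maxSteps <- min(maxSteps, ncol(X), n - 2L)
  best <- maxSteps
  if (n >= 12L && maxSteps >= 1L) {
    nf <- min(5L, n %/% 3L)
    foldid <- rep_len(seq_len(nf), n)[sample.int(n)]
    sse <- numeric(maxSteps + 1L)
    for (f in seq_len(nf)) {
      tr <- foldid != f
      path <- larPath(X[tr, , drop = FALSE], y[tr], maxSteps)
      avail <- nrow(path$beta) - 1L
      for (s in 0:maxSteps) {
        pred <- larPredict(path, min(s, avail), X[!tr, , drop = FALSE])
        sse[s + 1L] <- sse[s + 1L] + sum((y[!tr] - pred)^2)
      }
    }
    best <- which.min(sse) - 1L
  }
  path <- larPath(X, y, maxSteps)
  larPredict(path, min(best, nrow(path$beta) - 1L), testX)
}

# Principal components regression via SVD of the (already standardized)
# training matrix; components capped at the numerical rank.
pcrScore <- function(X, y, testX, ncomp) {
  xm <- colMeans(X)
  Xc <- sweep(X, 2, xm)
  sv <- svd(Xc)
  rank <- sum(sv$d > max(dim(Xc)) * .Machine$double.eps * sv$d[1])
  ncomp <- max(1L, min(ncomp, rank))
  V <- sv$v[, seq_len(ncomp), drop = FALSE]
  S <- Xc %*% V
  fit <- stats::lm.fit(cbind(1, S), y)
  St <- sweep(testX, 2, xm) %*% V
  drop(cbind(1, St) %*% fit$coefficients)
}

# SIMPLS weights for a univariate response.  Returns the p x ncomp weight
# matrix R (scores T = Xc R) and regression vector.
simplsFit <- function(X, y, ncomp) {
  n <- nrow(X); p <- ncol(X)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  ncomp <- max(1L, min(ncomp, p, n - 1L))
  R <- matrix(0, p, ncomp)
  Vb <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  s <- drop(crossprod(Xc, yc))
  a <- 0L
  for (j in seq_len(ncomp)) {
    r <- s
    tvec <- drop(Xc %*% r)
    nt <- sqrt(sum(tvec^2))
    if (!is.finite(nt) || nt < 1e-12) break
    tvec <- tvec / nt; r <- r / nt
    pvec <- drop(crossprod(Xc, tvec))
    q[j] <- sum(yc * tvec)
    v <- pvec
    if (j > 1L) {
      Vj <- Vb[, seq_len(j - 1L), drop = FALSE]
      v <- v - Vj %*% crossprod(Vj, pvec)
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) break
    v <- v / nv
    s <- s - v * sum(v * s)
    R[, j] <- r
    Vb[, j] <- v
    a <- j
  }
  if (a == 0L) stop("PLS found no usable component")
  R <- R[, seq_len(a), drop = FALSE]
  list(R = R, q = q[seq_len(a)], xm = xm, ym = ym,
       beta = drop(R %*% q[seq_len(a)]))
}

plsScore <- function(X, y, testX, ncomp) {
  fit <- simplsFit(X, y, ncomp)
  drop(sweep(testX, 2, fit$xm) %*% fit$beta) + fit$ym
}

# PLS-LDA: linear discriminant analysis on the SIMPLS score space; returns
# the posterior probability of class 1.
plsLdaScore <- function(X, y, testX, ncomp) {
  fit <- simplsFit(X, y, ncomp)
  Ttr <- sweep(X, 2, fit$xm) %*% fit$R
  Tte <- sweep(testX, 2, fit$xm) %*% fit$R
  colnames(Ttr) <- colnames(Tte) <- paste0("C", seq_len(ncol(Ttr)))
  lda <- MASS::lda(Ttr, grouping = factor(y, levels = c(0, 1)))
  post <- stats::predict(lda, Tte)$posterior
  as.numeric(post[, "1"])
}
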