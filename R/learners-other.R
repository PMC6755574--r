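# k-nearest neighbors (FNN backend), a single-hidden-layer neural network,
# and the radial-kernel SVM-type learner.
#
# No SVM library is available in this stack, so "SVM" is realized as a
# radial-basis-kernel regularized learner solved in the kernel dual: kernel
# logistic regression (IRLS) for binary responses, giving probabilities in
# (0, 1), and kernel ridge regression for continuous responses.  cost plays
# the usual role (regularization lambda = 1/(2 * cost)) and gamma the usual
# RBF width (default 1/p).  See the methods vignette for the rationale.

knnScore <- function(X, y, testX, k, binary) {
  k <- min(as.integer(k), nrow(X))
  if (binary) {
    cl <- factor(y, levels = c(0, 1))
    pred <- FNN::knn(X, testX, cl, k = k, prob = TRUE)
    win <- attr(pred, "prob")
    ifelse(pred == "1", win, 1 - win)
  } else {
    FNN::knn.reg(X, testX, y, k = k)$pred
  }
}

# Single hidden layer with logistic activations, trained by BFGS on a
# weight-decay-penalized loss (cross-entropy for binary, least squares for
# continuous).  Weights are initialized uniformly on [-0.5, 0.5] from the
# caller-seeded RNG.
nnetScore <- function(X, y, testX, size, decay, maxit, binary) {
  n <- nrow(X); p <- ncol(X); h <- as.integer(size)
  nw <- (p + 1L) * h + (h + 1L)
  sigm <- function(z) 1 / (1 + exp(-z))

  unpack <- function(w) {
    W1 <- matrix(w[seq_len((p + 1L) * h)], p + 1L, h)
    w2 <- w[(p + 1L) * h + seq_len(h + 1L)]
    list(W1 = W1, w2 = w2)
  }
  forward <- function(w, M) {
    par <- unpack(w)
    H <- sigm(cbind(1, M) %*% par$W1)
    out <- drop(cbind(1, H) %*% par$w2)
    list(H = H, out = out, par = par)
  }
  loss <- function(w) {
    fw <- forward(w, X)
    fit <- if (binary) {
      pr <- sigm(fw$out)
      -sum(y * log(pmax(pr, 1e-12)) + (1 - y) * log(pmax(1 - pr, 1e-12)))
    } else {
      0.5 * sum((y - fw$out)^2)
    }
    fit + 0.5 * decay * sum(w^2)
  }
  grad <- function(w) {
    fw <- forward(w, X)
    # residual of the output unit; identical algebra for both losses
    delta <- if (binary) sigm(fw$out) - y else fw$out - y
    gw2 <- drop(crossprod(cbind(1, fw$H), delta))
    back <- (delta %o% fw$par$w2[-1]) * fw$H * (1 - fw$H)
    gW1 <- crossprod(cbind(1, X), back)
    c(as.numeric(gW1), gw2) + decay * w
  }

  w0 <- stats::runif(nw, -0.5, 0.5)
  opt <- stats::optim(w0, loss, grad, method = "BFGS",
                      control = list(maxit = maxit))
  out <- forward(opt$par, testX)$out
  if (binary) sigm(out) else out
}

rbfKernel <- function(A, B, gamma) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

svmScore <- function(X, y, testX, cost, gamma, binary) {
  p <- ncol(X)
  if (is.null(gamma) || is.na(gamma)) gamma <- 1 / max(1L, p)
  lambda <- 1 / (2 * cost)
  n <- nrow(X)
  # +1 in the kernel supplies an implicit intercept
  K <- rbfKernel(X, X, gamma) + 1
  Kt <- rbfKernel(testX, X, gamma) + 1
  if (binary) {
    alpha <- rep(0, n)
    f <- drop(K %*% alpha)
    for (it in seq_len(25L)) {
      pr <- 1 / (1 + exp(-f))
      g <- (pr - y) + lambda * alpha
      W <- pmax(pr * (1 - pr), 1e-6)
      step <- solve(W * K + diag(lambda, n), -g)
      alpha <- alpha + step
      fNew <- drop(K %*% alpha)
      if (max(abs(fNew - f)) < 1e-8) { f <- fNew; break }
      f <- fNew
    }
    1 / (1 + exp(-drop(Kt %*% alpha)))
  } else {
    alpha <- solve(K + diag(lambda * n, n), y - mean(y))
    drop(Kt %*% alpha) + mean(y)
  }
}
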