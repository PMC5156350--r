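# Fisher discriminant with a ridge-stabilized pooled covariance. The ridge is
# expressed relative to the mean diagonal of the pooled covariance so the same
# lambda works across feature scalings; when p > n the solve goes through the
# Woodbury identity in sample space.

fitRidgeLDA <- function(X, labels, lambda = 0.1) {
  X <- as.matrix(X)
  y <- labels == "remembered"
  if (!any(y) || all(y))
    stop("LDA requires both classes in the training set")
  mu1 <- colMeans(X[y, , drop = FALSE])
  mu0 <- colMeans(X[!y, , drop = FALSE])
  n <- nrow(X)
  p <- ncol(X)
  Xc <- X
  Xc[y, ] <- sweep(X[y, , drop = FALSE], 2L, mu1)
  Xc[!y, ] <- sweep(X[!y, , drop = FALSE], 2L, mu0)
  nu <- max(n - 2L, 1L)
  d <- mu1 - mu0
  meanDiag <- sum(Xc^2) / (nu * p)
  lam <- max(lambda * meanDiag, 1e-10)
  if (p <= n) {
    S <- crossprod(Xc) / nu
    w <- solve(S + diag(lam, p), d)
  } else {
    C <- Xc / sqrt(nu)
    G <- tcrossprod(C)                      # n x n
    t1 <- solve(G + diag(lam, n), C %*% d)
    w <- (d - crossprod(C, t1)) / lam
  }
  w <- as.numeric(w)
  list(w = w, threshold = sum(w * (mu1 + mu0)) / 2, lambda = lambda)
}

# decision value > 0 (or = 0) -> remembered
predictRidgeLDA <- function(model, X, value = FALSE) {
  s <- as.matrix(X) %*% model$w - model$threshold
  if (value) return(as.numeric(s))
  ifelse(as.numeric(s) < 0, "forgotten", "remembered")
}
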