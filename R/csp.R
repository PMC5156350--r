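# Common spatial patterns: spatial filters maximizing the variance ratio
# between the two classes, from the generalized eigendecomposition of the
# class-average covariances (trial covariances trace-normalized first).

#' Common spatial pattern filters
#'
#' @param data trials x channels x samples array.
#' @param labels per-trial "remembered"/"forgotten".
#' @param nPairs number of filter pairs (top + bottom eigenvectors).
#' @param ridge relative ridge added to the composite covariance; 0 by
#'   default (near-null directions are truncated instead), set positive for
#'   rank-deficient covariances.
#' @return list with \code{filters} (2*nPairs x channels matrix, rows are
#'   spatial filters) and \code{eigenvalues} of the remembered-class share.
#' @export
cspFilters <- function(data, labels, nPairs = 2L, ridge = 0) {
  classCov <- function(idx) {
    S <- 0
    for (i in idx) {
      Xi <- data[i, , ]
      Ci <- tcrossprod(Xi - rowMeans(Xi))
      S <- S + Ci / sum(diag(Ci))
    }
    S / length(idx)
  }
  i1 <- which(labels == "remembered")
  i0 <- which(labels == "forgotten")
  if (!length(i1) || !length(i0))
    stop("CSP requires both classes")
  C1 <- classCov(i1)
  C0 <- classCov(i0)
  Cc <- C0 + C1
  if (ridge > 0) Cc <- Cc + diag(ridge * mean(diag(Cc)), nrow(Cc))
  ec <- eigen(Cc, symmetric = TRUE)
  keep <- ec$values > 1e-12 * ec$values[1L]
  W <- diag(1 / sqrt(ec$values[keep])) %*% t(ec$vectors[, keep, drop = FALSE])
  S1 <- W %*% C1 %*% t(W)
  e1 <- eigen((S1 + t(S1)) / 2, symmetric = TRUE)
  B <- t(e1$vectors) %*% W
  nf <- nrow(B)
  nPairs <- min(nPairs, nf %/% 2L)
  sel <- c(seq_len(nPairs), nf - seq_len(nPairs) + 1L)
  list(filters = B[sel, , drop = FALSE],
       eigenvalues = e1$values[sel],
       allEigenvalues = e1$values)
}

# log-variance CSP features for one trial (channels x samples)
cspFeatures <- function(filters, trial) {
  proj <- filters %*% (trial - rowMeans(trial))
  v <- apply(proj, 1L, stats::var)
  log(v / sum(v))
}
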