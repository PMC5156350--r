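# Independent reference implementations used as oracles. These deliberately
# use naive explicit loops and share no code with the package internals.

sigmoidRef <- function(u) 1 / (1 + exp(-u))

# naive triple-loop feedforward for the five-layer network
naiveForward <- function(params, cfg, input) {
  a <- cfg@a
  b <- cfg@b
  nC <- cfg@nC
  tLen <- cfg@tLen
  k <- cfg@tLen %/% cfg@p
  xc <- matrix(0, tLen, nC)
  for (m in seq_len(nC)) {
    for (t in seq_len(tLen)) {
      u <- params@spatialBias[m]
      for (d in seq_len(cfg@nCh))
        u <- u + params@spatialKernels[m, d] * input[d, t]
      xc[t, m] <- a * tanh(b * u)
    }
  }
  xcs <- list()
  for (m in seq_len(nC)) {
    v <- numeric(cfg@p[m])
    for (p in seq_len(cfg@p[m])) {
      u <- params@temporalBias[m]
      for (j in seq_len(k[m]))
        u <- u + params@temporalKernels[[m]][j] * xc[(p - 1) * k[m] + j, m]
      v[p] <- a * tanh(b * u)
    }
    xcs[[m]] <- v
  }
  vcat <- unlist(xcs)
  xh <- numeric(cfg@q)
  for (q in seq_len(cfg@q))
    xh[q] <- sigmoidRef(sum(params@hiddenW[q, ] * vcat) + params@hiddenB[q])
  z <- numeric(2)
  for (i in 1:2)
    z[i] <- sigmoidRef(sum(params@outW[i, ] * xh) + params@outB[i])
  list(z = z, xc = xc, xcs = xcs, xh = xh)
}

naiveLoss <- function(params, cfg, input, target) {
  z <- naiveForward(params, cfg, input)$z
  0.5 * sum((z - target)^2)
}

# central finite-difference gradient of the half squared error
finiteDiffGrad <- function(params, cfg, input, target, eps = 1e-5) {
  flat <- conveegnn:::flattenParams(params)
  g <- numeric(length(flat))
  for (j in seq_along(flat)) {
    up <- flat
    dn <- flat
    up[j] <- up[j] + eps
    dn[j] <- dn[j] - eps
    g[j] <- (naiveLoss(conveegnn:::unflattenParams(up, cfg), cfg, input,
                       target) -
             naiveLoss(conveegnn:::unflattenParams(dn, cfg), cfg, input,
                       target)) / (2 * eps)
  }
  g
}

randomSmallConfig <- function() {
  nCh <- sample(2:6, 1)
  nC <- sample(1:3, 1)
  p <- integer(nC)
  tLen <- sample(c(6L, 8L, 12L, 15L, 20L), 1)
  for (m in seq_len(nC)) {
    divs <- setdiff(which(tLen %% seq_len(tLen) == 0L), tLen)
    p[m] <- sample(divs, 1)
  }
  networkConfig(nCh = nCh, tLen = tLen, nC = nC, p = p,
                q = sample(2:6, 1), seed = NA)
}
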