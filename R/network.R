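#' Construct a network configuration
#'
#' @param nCh input channels (default 30, the montage minus EOG).
#' @param tLen input length T: 75 for the entire window, 30 for pre/during.
#' @param nC number of spatial maps.
#' @param p integer vector of temporal map sizes P_m; every P_m must divide
#'   \code{tLen} (K_m = T / P_m receptive fields).
#' @param q hidden layer size (10).
#' @param a,b scaled-tanh constants (1.7159 and 2/3).
#' @param learningRate,maxEpochs,patience,valFraction SGD settings.
#' @param nRestarts independent random initializations per fit; the run with
#'   the lowest validation MSE on the one shared split is kept (per-sample
#'   SGD on this loss surface is sensitive to the starting point).
#' @param init "uniform" draws each weight of an n-input neuron from
#'   \code{[-1/sqrt(n), 1/sqrt(n)]}; "gaussian" uses SD \code{1/sqrt(n)}.
#' @param seed integer seed (NA uses the caller's RNG state).
#' @return a [NetworkConfig-class].
#' @export
#' @examples
#' cfg <- networkConfig(nCh = 30, tLen = 75, nC = 1, p = 3)
#' countParams(cfg)
networkConfig <- function(nCh = 30L, tLen = 75L, nC = 1L, p = 3L, q = 10L,
                          a = 1.7159, b = 2 / 3, learningRate = 0.01,
                          maxEpochs = 400L, patience = 25L,
                          valFraction = 0.3, nRestarts = 5L,
                          init = "uniform", seed = NA) {
  new("NetworkConfig", nCh = as.integer(nCh), tLen = as.integer(tLen),
      nC = as.integer(nC), p = as.integer(p), q = as.integer(q),
      a = a, b = b, learningRate = learningRate,
      maxEpochs = as.integer(maxEpochs), patience = as.integer(patience),
      valFraction = valFraction, nRestarts = as.integer(nRestarts),
      init = init, seed = as.integer(seed))
}

cfgToList <- function(cfg) {
  list(nCh = cfg@nCh, tLen = cfg@tLen, nC = cfg@nC, p = cfg@p, q = cfg@q,
       a = cfg@a, b = cfg@b)
}

#' Per-layer trainable parameter and connection counts
#'
#' The spatial layer has \code{nC * (M + 1)} trainable parameters (M = nCh)
#' and \code{T * nC * (M + 1)} connections; the temporal layer
#' \code{sum(K_m + 1)} parameters and \code{sum(P_m * (K_m + 1))} connections;
#' the hidden layer \code{Q * (sum(P_m) + 1)}; the output layer
#' \code{2 * (Q + 1)}.
#'
#' @param cfg a [NetworkConfig-class].
#' @return list with \code{parameters} and \code{connections} per layer and
#'   \code{total} trainable parameters.
#' @export
countParams <- function(cfg) {
  validObject(cfg)
  k <- cfg@tLen %/% cfg@p
  params <- list(
    Lc   = cfg@nC * (cfg@nCh + 1L),
    Lcs  = sum(k + 1L),
    Lh   = cfg@q * (sum(cfg@p) + 1L),
    Lout = 2L * (cfg@q + 1L))
  conns <- list(
    Lc  = cfg@tLen * cfg@nC * (cfg@nCh + 1L),
    Lcs = sum(cfg@p * (k + 1L)))
  list(parameters = params, connections = conns,
       total = sum(unlist(params)))
}

drawWeights <- function(n, nIn, init) {
  bound <- 1 / sqrt(nIn)
  if (init == "uniform") stats::runif(n, -bound, bound)
  else stats::rnorm(n, 0, bound)
}

#' Initialize network parameters
#'
#' Every weight and bias of a neuron with n inputs is drawn from a
#' distribution scaled by \code{1/sqrt(n)} (uniform on
#' \code{[-1/sqrt(n), 1/sqrt(n)]} by default).
#'
#' @param cfg a [NetworkConfig-class]; \code{cfg@seed} (if not NA) makes the
#'   draw reproducible.
#' @return a [NetworkParams-class].
#' @export
initParams <- function(cfg) {
  validObject(cfg)
  withSeed(cfg@seed, {
    k <- cfg@tLen %/% cfg@p
    sp <- sum(cfg@p)
    new("NetworkParams",
        spatialKernels = matrix(drawWeights(cfg@nC * cfg@nCh, cfg@nCh,
                                            cfg@init), cfg@nC, cfg@nCh),
        spatialBias = drawWeights(cfg@nC, cfg@nCh, cfg@init),
        temporalKernels = lapply(k, function(km)
          drawWeights(km, km, cfg@init)),
        temporalBias = vapply(k, function(km)
          drawWeights(1L, km, cfg@init), numeric(1)),
        hiddenW = matrix(drawWeights(cfg@q * sp, sp, cfg@init), cfg@q, sp,
                         byrow = TRUE),
        hiddenB = drawWeights(cfg@q, sp, cfg@init),
        outW = matrix(drawWeights(2L * cfg@q, cfg@q, cfg@init), 2L, cfg@q,
                      byrow = TRUE),
        outB = drawWeights(2L, cfg@q, cfg@init))
  })
}

# flat layout shared with the C++ core
flattenParams <- function(params) {
  nC <- nrow(params@spatialKernels)
  c(as.vector(t(cbind(params@spatialKernels, params@spatialBias))),
    unlist(lapply(seq_len(nC), function(m)
      c(params@temporalKernels[[m]], params@temporalBias[m]))),
    as.vector(t(cbind(params@hiddenW, params@hiddenB))),
    as.vector(t(cbind(params@outW, params@outB))))
}

unflattenParams <- function(flat, cfg) {
  k <- cfg@tLen %/% cfg@p
  sp <- sum(cfg@p)
  pos <- 0L
  take <- function(n) {
    out <- flat[pos + seq_len(n)]
    pos <<- pos + n
    out
  }
  spat <- matrix(take(cfg@nC * (cfg@nCh + 1L)), cfg@nC, cfg@nCh + 1L,
                 byrow = TRUE)
  tk <- vector("list", cfg@nC)
  tb <- numeric(cfg@nC)
  for (m in seq_len(cfg@nC)) {
    v <- take(k[m] + 1L)
    tk[[m]] <- v[seq_len(k[m])]
    tb[m] <- v[k[m] + 1L]
  }
  hid <- matrix(take(cfg@q * (sp + 1L)), cfg@q, sp + 1L, byrow = TRUE)
  out <- matrix(take(2L * (cfg@q + 1L)), 2L, cfg@q + 1L, byrow = TRUE)
  new("NetworkParams",
      spatialKernels = spat[, seq_len(cfg@nCh), drop = FALSE],
      spatialBias = spat[, cfg@nCh + 1L],
      temporalKernels = tk, temporalBias = tb,
      hiddenW = hid[, seq_len(sp), drop = FALSE], hiddenB = hid[, sp + 1L],
      outW = out[, seq_len(cfg@q), drop = FALSE], outB = out[, cfg@q + 1L])
}

#' Feedforward pass
#'
#' Runs one N_ch x T input matrix through the network and returns the full
#' trace: spatial map outputs (length T each), temporal map outputs (length
#' P_m each), hidden activations and the two output activations
#' \code{(Z0, Z1)}.
#'
#' @param params a [NetworkParams-class].
#' @param cfg the matching [NetworkConfig-class].
#' @param input numeric N_ch x T matrix.
#' @return list with elements \code{z}, \code{xc} (T x nC matrix),
#'   \code{xcs} (list per map), \code{xh}.
#' @export
forwardPass <- function(params, cfg, input) {
  input <- as.matrix(input)
  if (nrow(input) != cfg@nCh || ncol(input) != cfg@tLen)
    stop("input must be ", cfg@nCh, " x ", cfg@tLen)
  .nnForwardCpp(cfgToList(cfg), flattenParams(params), input)
}

#' Backpropagation gradients
#'
#' Gradients of the half squared error \code{E = 0.5 * sum((Z - target)^2)}
#' with respect to every parameter, with shared-kernel gradients accumulated
#' over all positions of each map.
#'
#' @param params,cfg,input as in [forwardPass()].
#' @param target length-2 numeric, \code{c(1, 0)} for forgotten or
#'   \code{c(0, 1)} for remembered.
#' @return list with \code{gradient} (a [NetworkParams-class] of the same
#'   shape), \code{loss} and \code{z}.
#' @export
backwardPass <- function(params, cfg, input, target) {
  r <- .nnGradCpp(cfgToList(cfg), flattenParams(params), as.matrix(input),
                  as.numeric(target))
  list(gradient = unflattenParams(r$grad, cfg), loss = r$loss, z = r$z)
}

labelToY <- function(labels) as.integer(labels == "remembered")

targetMatrix <- function(labels) {
  t(vapply(labels, function(l)
    if (l == "remembered") c(0, 1) else c(1, 0), numeric(2)))
}

# stratified split + minority duplication, shared by the conv net and the
# ANN baselines; returns integer index vectors into the input list
balancedSplit <- function(labels, valFraction) {
  idx <- seq_along(labels)
  valIdx <- integer(0)
  for (cl in unique(labels)) {
    clIdx <- idx[labels == cl]
    nVal <- floor(length(clIdx) * valFraction)
    if (nVal > 0L)
      valIdx <- c(valIdx, sample(clIdx, nVal))
  }
  trIdx <- setdiff(idx, valIdx)
  # duplicate minority-class training samples cyclically until balanced
  tab <- table(factor(labels[trIdx], c("remembered", "forgotten")))
  if (min(tab) > 0L && tab[1L] != tab[2L]) {
    minor <- names(tab)[which.min(tab)]
    minorIdx <- trIdx[labels[trIdx] == minor]
    need <- max(tab) - min(tab)
    extra <- rep_len(minorIdx, need)
    trIdx <- c(trIdx, extra)
  }
  list(train = trIdx, val = valIdx)
}

#' Train the network
#'
#' Splits the labeled inputs into a stratified 70/30 train/validation split,
#' duplicates minority-class training samples cyclically until the classes
#' are balanced, then runs per-sample stochastic gradient descent with
#' epoch-wise reshuffling, stopping when the validation mean-square error has
#' not improved for \code{patience} epochs (the parameters achieving the
#' minimum validation error are returned).
#'
#' @param inputs list of N_ch x T matrices, or a [ModelInputSet-class].
#' @param labels character "remembered"/"forgotten" (taken from the input set
#'   if omitted).
#' @param cfg a [NetworkConfig-class]; \code{cfg@seed} governs
#'   initialization, the split and the shuffles.
#' @return a [TrainResult-class].
#' @export
trainNetwork <- function(inputs, labels = NULL, cfg = networkConfig()) {
  if (is(inputs, "ModelInputSet")) {
    if (is.null(labels)) labels <- trialLabels(inputs)
    inputs <- inputMatrices(inputs)
  }
  chkLabels(labels)
  if (length(unique(labels)) < 2L)
    stop("training requires at least one sample of each class")
  if (length(inputs) != length(labels))
    stop("inputs and labels length mismatch")
  d <- dim(inputs[[1L]])
  if (d[1L] != cfg@nCh || d[2L] != cfg@tLen)
    stop("inputs must be ", cfg@nCh, " x ", cfg@tLen,
         " to match the network configuration")
  withSeed(cfg@seed, {
    sp <- balancedSplit(labels, cfg@valFraction)
    initCfg <- networkConfig(cfg@nCh, cfg@tLen, cfg@nC, cfg@p, cfg@q,
                             cfg@a, cfg@b, init = cfg@init, seed = NA)
    best <- NULL
    bestVal <- Inf
    for (r in seq_len(max(cfg@nRestarts, 1L))) {
      p0 <- flattenParams(initParams(initCfg))
      fit <- .nnTrainCpp(cfgToList(cfg), p0,
                         inputs[sp$train], labelToY(labels[sp$train]),
                         inputs[sp$val], labelToY(labels[sp$val]),
                         cfg@learningRate, cfg@maxEpochs, cfg@patience)
      v <- min(fit$valMSE)
      if (v < bestVal) {
        bestVal <- v
        best <- fit
      }
    }
    new("TrainResult",
        params = unflattenParams(best$params, cfg), config = cfg,
        history = data.frame(epoch = seq_along(best$trainMSE),
                             trainMSE = best$trainMSE, valMSE = best$valMSE),
        stoppedEpoch = as.integer(best$stoppedEpoch),
        bestEpoch = as.integer(best$bestEpoch))
  })
}

#' Predict the class of input matrices
#'
#' An input is predicted forgotten if the first output neuron Z0 exceeds the
#' second (Z1), and remembered otherwise (ties fall to remembered).
#'
#' @param params a [NetworkParams-class] (or a [TrainResult-class]).
#' @param cfg the matching [NetworkConfig-class] (ignored when \code{params}
#'   is a [TrainResult-class]).
#' @param inputs a single N_ch x T matrix or a list of them.
#' @return character vector of "remembered"/"forgotten".
#' @export
predictLabel <- function(params, cfg = NULL, inputs) {
  if (is(params, "TrainResult")) {
    cfg <- params@config
    params <- params@params
  }
  if (is.matrix(inputs)) inputs <- list(inputs)
  z <- .nnPredictCpp(cfgToList(cfg), flattenParams(params), inputs)
  ifelse(z[, 1L] > z[, 2L], "forgotten", "remembered")
}

#' Extract per-trial input matrices from a ModelInputSet
#'
#' @param x a [ModelInputSet-class].
#' @return list of N_ch x T matrices.
#' @export
inputMatrices <- function(x) {
  lapply(seq_len(nTrials(x)), function(i) x@data[i, , ])
}
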