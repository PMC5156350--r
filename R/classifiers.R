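# The seven classifiers behind one common contract: prepareContext() does
# label-free feature precomputation once per dataset, fitClassifier() trains
# on one fold's training trials only, predictClassifier() labels held-out
# trials. crossValidate() drives them all through the identical fold plan.

#' Construct a classifier specification
#'
#' @param name one of "conveegnn", "lda", "ann1", "ann2", "svm", "svmlda",
#'   "cwtsvm".
#' @param ... overrides for the model's hyperparameters: \code{config}
#'   (conveegnn), \code{lambda} (lda), \code{learningRate}/\code{maxEpochs}/
#'   \code{patience} (ann1, ann2), \code{degree}/\code{costGrid} (svm),
#'   \code{nPairs}/\code{rule} (svmlda), \code{bands}/\code{cycles} (cwtsvm).
#' @return a [ClassifierSpec-class] subclass instance.
#' @export
#' @examples
#' classifierSpec("conveegnn", config = networkConfig(nC = 1, p = 3))
#' classifierSpec("lda")
classifierSpec <- function(name, ...) {
  args <- list(...)
  pick <- function(key, default) if (key %in% names(args)) args[[key]] else default
  switch(name,
    conveegnn = new("ConvEEGNNSpec", name = "conveegnn",
                    config = pick("config", networkConfig())),
    lda = new("LDASpec", name = "lda", lambda = pick("lambda", 0.1)),
    ann1 = new("ANNSpec", name = "ann1", hidden = 10L,
               learningRate = pick("learningRate", 0.01),
               maxEpochs = as.integer(pick("maxEpochs", 500L)),
               patience = as.integer(pick("patience", 20L))),
    ann2 = new("ANNSpec", name = "ann2", hidden = c(20L, 10L),
               learningRate = pick("learningRate", 0.01),
               maxEpochs = as.integer(pick("maxEpochs", 500L)),
               patience = as.integer(pick("patience", 20L))),
    svm = new("SVMSpec", name = "svm", degree = as.integer(pick("degree", 3L)),
              costGrid = pick("costGrid", c(0.1, 1, 10))),
    svmlda = new("SVMLDAFusionSpec", name = "svmlda",
                 nPairs = as.integer(pick("nPairs", 2L)),
                 rule = pick("rule", "mean")),
    cwtsvm = new("CWTSVMSpec", name = "cwtsvm",
                 bands = pick("bands", c(4.00, 6.42, 11.26)),
                 cycles = pick("cycles", 6)),
    stop("unknown classifier: ", name)
  )
}

# ---- shared helpers ---------------------------------------------------------

# decimate + crop without normalization (label-free)
decCrop <- function(epochs, window, targetRate = 25) {
  bounds <- windowBounds(window)
  dec <- decimateEpochs(epochs, targetRate)
  idx <- windowIndices(bounds[1L], bounds[2L], dec@tStart, targetRate)
  list(arr = dec@data[, , idx, drop = FALSE],
       channelNames = dec@channelNames)
}

chanStats <- function(arr, idx, channelNames) {
  sub <- arr[idx, , , drop = FALSE]
  mu <- apply(sub, 2L, mean)
  sdv <- apply(sub, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  list(mean = stats::setNames(mu, channelNames),
       sd = stats::setNames(sdv, channelNames))
}

applyStats <- function(arr, stats) {
  for (ch in seq_len(dim(arr)[2L]))
    arr[, ch, ] <- (arr[, ch, ] - stats$mean[[ch]]) / stats$sd[[ch]]
  arr
}

flattenArr <- function(arr, idx = seq_len(dim(arr)[1L])) {
  t(vapply(idx, function(i) as.vector(arr[i, , ]),
           numeric(prod(dim(arr)[2:3]))))
}

inputContext <- function(epochs, window) {
  dc <- decCrop(epochs, window)
  list(arr = dc$arr, channelNames = dc$channelNames,
       labels = trialLabels(epochs), window = window)
}

yFactor <- function(labels) factor(labels, levels = c("forgotten", "remembered"))

stratSplit <- function(labels, valFraction = 0.3) {
  idx <- seq_along(labels)
  valIdx <- integer(0)
  for (cl in unique(labels)) {
    clIdx <- idx[labels == cl]
    nVal <- floor(length(clIdx) * valFraction)
    if (nVal > 0L) valIdx <- c(valIdx, sample(clIdx, nVal))
  }
  list(train = setdiff(idx, valIdx), val = valIdx)
}

# ---- ConvEEGNN --------------------------------------------------------------

setMethod("prepareContext", "ConvEEGNNSpec",
  function(spec, epochs, window = "entire") inputContext(epochs, window))

setMethod("fitClassifier", "ConvEEGNNSpec",
  function(spec, context, trainIdx, seed = NULL) {
    st <- chanStats(context$arr, trainIdx, context$channelNames)
    arr <- applyStats(context$arr[trainIdx, , , drop = FALSE], st)
    tpl <- spec@config
    cfg <- networkConfig(nCh = dim(arr)[2L], tLen = dim(arr)[3L],
                         nC = tpl@nC, p = tpl@p, q = tpl@q, a = tpl@a,
                         b = tpl@b, learningRate = tpl@learningRate,
                         maxEpochs = tpl@maxEpochs, patience = tpl@patience,
                         valFraction = tpl@valFraction, init = tpl@init,
                         seed = if (is.null(seed)) tpl@seed else seed)
    inputs <- lapply(seq_len(dim(arr)[1L]), function(i) arr[i, , ])
    fit <- trainNetwork(inputs, context$labels[trainIdx], cfg)
    list(fit = fit, stats = st)
  })

setMethod("predictClassifier", "ConvEEGNNSpec",
  function(spec, model, context, testIdx) {
    arr <- applyStats(context$arr[testIdx, , , drop = FALSE], model$stats)
    inputs <- lapply(seq_along(testIdx), function(i) arr[i, , ])
    predictLabel(model$fit, inputs = inputs)
  })

# ---- LDA --------------------------------------------------------------------

setMethod("prepareContext", "LDASpec",
  function(spec, epochs, window = "entire") inputContext(epochs, window))

setMethod("fitClassifier", "LDASpec",
  function(spec, context, trainIdx, seed = NULL) {
    st <- chanStats(context$arr, trainIdx, context$channelNames)
    X <- flattenArr(applyStats(context$arr, st), trainIdx)
    list(lda = fitRidgeLDA(X, context$labels[trainIdx], spec@lambda),
         stats = st)
  })

setMethod("predictClassifier", "LDASpec",
  function(spec, model, context, testIdx) {
    X <- flattenArr(applyStats(context$arr, model$stats), testIdx)
    predictRidgeLDA(model$lda, X)
  })

# ---- fully connected ANNs ---------------------------------------------------

# shared SGD machinery: stratified 70/30 split, minority duplication,
# per-sample updates with early stopping (the same scheme as the conv net)
trainMLP <- function(X, labels, hidden, learningRate, maxEpochs, patience,
                     seed = NULL, a = 1.7159, b = 2 / 3) {
  sizes <- as.integer(c(ncol(X), hidden, 2L))
  acts <- as.integer(c(1L, rep(2L, length(hidden))))
  withSeed(seed, {
    nP <- .mlpCountParamsCpp(sizes, acts)
    p0 <- numeric(nP)
    off <- 0L
    for (l in seq_len(length(sizes) - 1L)) {
      nIn <- sizes[l]
      nW <- sizes[l + 1L] * (nIn + 1L)
      p0[off + seq_len(nW)] <- stats::runif(nW, -1 / sqrt(nIn), 1 / sqrt(nIn))
      off <- off + nW
    }
    sp <- balancedSplit(labels, 0.3)
    .mlpTrainCpp(sizes, acts, a, b, p0,
                 X[sp$train, , drop = FALSE], labelToY(labels[sp$train]),
                 X[sp$val, , drop = FALSE], labelToY(labels[sp$val]),
                 learningRate, maxEpochs, patience)
  })
}

predictMLP <- function(fit, X, hidden, a = 1.7159, b = 2 / 3) {
  sizes <- as.integer(c(ncol(X), hidden, 2L))
  acts <- as.integer(c(1L, rep(2L, length(hidden))))
  z <- .mlpPredictCpp(sizes, acts, a, b, fit$params, X)
  ifelse(z[, 1L] > z[, 2L], "forgotten", "remembered")
}

setMethod("prepareContext", "ANNSpec",
  function(spec, epochs, window = "entire") inputContext(epochs, window))

setMethod("fitClassifier", "ANNSpec",
  function(spec, context, trainIdx, seed = NULL) {
    st <- chanStats(context$arr, trainIdx, context$channelNames)
    X <- flattenArr(applyStats(context$arr, st), trainIdx)
    fit <- trainMLP(X, context$labels[trainIdx], spec@hidden,
                    spec@learningRate, spec@maxEpochs, spec@patience, seed)
    list(fit = fit, stats = st)
  })

setMethod("predictClassifier", "ANNSpec",
  function(spec, model, context, testIdx) {
    X <- flattenArr(applyStats(context$arr, model$stats), testIdx)
    predictMLP(model$fit, X, spec@hidden)
  })

# ---- cubic polynomial SVM ---------------------------------------------------

svmDecision <- function(fit, X) {
  pr <- stats::predict(fit, X, decision.values = TRUE)
  dv <- as.numeric(attr(pr, "decision.values"))
  pos <- sub("/.*", "", colnames(attr(pr, "decision.values"))[1L])
  if (pos == "remembered") dv else -dv
}

fitCubicSVM <- function(X, labels, degree = 3L, costGrid = c(0.1, 1, 10),
                        seed = NULL) {
  y <- yFactor(labels)
  cost <- costGrid[1L]
  if (length(costGrid) > 1L) {
    sp <- withSeed(seed, stratSplit(labels, 0.3))
    if (length(sp$val) >= 2L &&
        length(unique(labels[sp$train])) == 2L &&
        length(unique(labels[sp$val])) == 2L) {
      accs <- vapply(costGrid, function(cc) {
        f <- e1071::svm(X[sp$train, , drop = FALSE], y[sp$train],
                        kernel = "polynomial", degree = degree, coef0 = 1,
                        cost = cc, scale = FALSE)
        mean(stats::predict(f, X[sp$val, , drop = FALSE]) == y[sp$val])
      }, numeric(1))
      cost <- costGrid[which.max(accs)]
    }
  }
  e1071::svm(X, y, kernel = "polynomial", degree = degree, coef0 = 1,
             cost = cost, scale = FALSE)
}

setMethod("prepareContext", "SVMSpec",
  function(spec, epochs, window = "entire") inputContext(epochs, window))

setMethod("fitClassifier", "SVMSpec",
  function(spec, context, trainIdx, seed = NULL) {
    st <- chanStats(context$arr, trainIdx, context$channelNames)
    X <- flattenArr(applyStats(context$arr, st), trainIdx)
    list(fit = fitCubicSVM(X, context$labels[trainIdx], spec@degree,
                           spec@costGrid, seed),
         stats = st)
  })

setMethod("predictClassifier", "SVMSpec",
  function(spec, model, context, testIdx) {
    X <- flattenArr(applyStats(context$arr, model$stats), testIdx)
    as.character(stats::predict(model$fit, X))
  })

# ---- CSP/SVM + LDA fusion ---------------------------------------------------

setMethod("prepareContext", "SVMLDAFusionSpec",
  function(spec, epochs, window = "entire") {
    fs <- epochs@samplingRate
    preIdx <- windowIndices(0.3, 1.5, epochs@tStart, fs)
    durIdx <- windowIndices(1.5, 2.7, epochs@tStart, fs)
    durDec <- decCrop(epochs, "during")
    list(pre500 = epochs@data[, , preIdx, drop = FALSE],
         dur500 = epochs@data[, , durIdx, drop = FALSE],
         durDec = durDec$arr, channelNames = durDec$channelNames,
         labels = trialLabels(epochs))
  })

setMethod("fitClassifier", "SVMLDAFusionSpec",
  function(spec, context, trainIdx, seed = NULL) {
    lab <- context$labels[trainIdx]
    branchSVM <- function(arr) {
      csp <- cspFilters(arr[trainIdx, , , drop = FALSE], lab, spec@nPairs)
      feat <- t(vapply(trainIdx, function(i)
        cspFeatures(csp$filters, arr[i, , ]), numeric(2L * spec@nPairs)))
      # low-dimensional log-variance features: fixed unit cost
      fit <- fitCubicSVM(feat, lab, costGrid = 1, seed = seed)
      dv <- svmDecision(fit, feat)
      list(csp = csp, fit = fit, mu = mean(dv), sd = max(stats::sd(dv), 1e-9))
    }
    pre <- branchSVM(context$pre500)
    dur <- branchSVM(context$dur500)
    st <- chanStats(context$durDec, trainIdx, context$channelNames)
    X <- flattenArr(applyStats(context$durDec, st), trainIdx)
    ldaFit <- fitRidgeLDA(X, lab)
    dvL <- predictRidgeLDA(ldaFit, X, value = TRUE)
    list(pre = pre, dur = dur, lda = ldaFit, ldaStats = st,
         ldaMu = mean(dvL), ldaSd = max(stats::sd(dvL), 1e-9))
  })

setMethod("predictClassifier", "SVMLDAFusionSpec",
  function(spec, model, context, testIdx) {
    branchDV <- function(branch, arr) {
      feat <- t(vapply(testIdx, function(i)
        cspFeatures(branch$csp$filters, arr[i, , ]),
        numeric(nrow(branch$csp$filters))))
      (svmDecision(branch$fit, feat) - branch$mu) / branch$sd
    }
    z1 <- branchDV(model$pre, context$pre500)
    z2 <- branchDV(model$dur, context$dur500)
    X <- flattenArr(applyStats(context$durDec, model$ldaStats), testIdx)
    z3 <- (predictRidgeLDA(model$lda, X, value = TRUE) - model$ldaMu) /
      model$ldaSd
    s <- if (spec@rule == "vote") sign(z1) + sign(z2) + sign(z3)
         else (z1 + z2 + z3) / 3
    ifelse(s < 0, "forgotten", "remembered")
  })

# ---- Morlet band power + L1 linear classifier -------------------------------

setMethod("prepareContext", "CWTSVMSpec",
  function(spec, epochs, window = "entire") {
    list(features = cwtFeatureMatrix(epochs, spec@bands, spec@cycles),
         labels = trialLabels(epochs))
  })

setMethod("fitClassifier", "CWTSVMSpec",
  function(spec, context, trainIdx, seed = NULL) {
    X <- context$features[trainIdx, , drop = FALSE]
    y <- yFactor(context$labels[trainIdx])
    withSeed(seed, {
      cv <- tryCatch(
        suppressWarnings(
          glmnet::cv.glmnet(X, y, family = "binomial", alpha = 1,
                            nfolds = 5, type.measure = "class")),
        error = function(e)
          glmnet::glmnet(X, y, family = "binomial", alpha = 1,
                         lambda = 0.05))
      list(fit = cv)
    })
  })

setMethod("predictClassifier", "CWTSVMSpec",
  function(spec, model, context, testIdx) {
    X <- context$features[testIdx, , drop = FALSE]
    s <- if (inherits(model$fit, "cv.glmnet")) "lambda.min" else NULL
    p <- stats::predict(model$fit, X, s = s, type = "response")
    ifelse(as.numeric(p) < 0.5, "forgotten", "remembered")
  })
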