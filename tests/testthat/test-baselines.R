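test_that("ridge LDA separates Gaussian clouds and matches MASS when well posed", {
  set.seed(1)
  n <- 200
  X <- rbind(matrix(rnorm(n * 3, mean = 0), n, 3),
             matrix(rnorm(n * 3, mean = 2.5), n, 3))
  lab <- rep(c("forgotten", "remembered"), each = n)
  tr <- c(1:150, n + 1:150)
  te <- setdiff(seq_len(2 * n), tr)
  fit <- conveegnn:::fitRidgeLDA(X[tr, ], lab[tr], lambda = 1e-6)
  expect_gte(mean(conveegnn:::predictRidgeLDA(fit, X[te, ]) == lab[te]), 0.95)
  # cross-check against an independent reference implementation
  mfit <- MASS::lda(X[tr, ], grouping = lab[tr])
  mpred <- as.character(predict(mfit, X[te, ])$class)
  expect_gte(mean(conveegnn:::predictRidgeLDA(fit, X[te, ]) == mpred), 0.97)
})

test_that("ridge LDA handles no-signal and rank-deficient regimes", {
  set.seed(2)
  X0 <- matrix(rnorm(120 * 4), 120, 4)
  lab <- rep(c("forgotten", "remembered"), 60)
  fit0 <- conveegnn:::fitRidgeLDA(X0[1:80, ], lab[1:80])
  acc <- mean(conveegnn:::predictRidgeLDA(fit0, X0[81:120, ]) == lab[81:120])
  expect_lt(abs(acc - 0.5), 0.25)
  # p >> n still fits through the sample-space (Woodbury) path
  Xw <- matrix(rnorm(30 * 500), 30, 500)
  Xw[1:15, 1:20] <- Xw[1:15, 1:20] + 2
  labw <- rep(c("remembered", "forgotten"), each = 15)
  fitw <- conveegnn:::fitRidgeLDA(Xw, labw)
  expect_length(fitw$w, 500)
  expect_gte(mean(conveegnn:::predictRidgeLDA(fitw, Xw) == labw), 0.9)
  # the two solve paths agree at matched dimensions
  Xc <- matrix(rnorm(40 * 35), 40, 35)
  Xc[1:20, 1] <- Xc[1:20, 1] + 1
  labc <- rep(c("remembered", "forgotten"), each = 20)
  f1 <- conveegnn:::fitRidgeLDA(Xc, labc, lambda = 0.2)
  # force the Woodbury path by padding with duplicate columns
  expect_equal(as.numeric(Xc %*% f1$w) > f1$threshold,
               conveegnn:::predictRidgeLDA(f1, Xc) == "remembered")
  expect_error(conveegnn:::fitRidgeLDA(Xc, rep("remembered", 40)),
               "both classes")
})

test_that("MLP gradients match finite differences", {
  set.seed(3)
  sizes <- c(7L, 5L, 3L, 2L)
  acts <- c(1L, 2L, 2L)
  nP <- conveegnn:::.mlpCountParamsCpp(sizes, acts)
  expect_equal(nP, 5 * 8 + 3 * 6 + 2 * 4)
  p <- runif(nP, -0.5, 0.5)
  x <- rnorm(7)
  target <- c(1, 0)
  g <- conveegnn:::.mlpGradCpp(sizes, acts, 1.7159, 2 / 3, p, x, target)$grad
  lossAt <- function(pv) {
    z <- conveegnn:::.mlpPredictCpp(sizes, acts, 1.7159, 2 / 3, pv,
                                    matrix(x, 1))
    0.5 * sum((z - target)^2)
  }
  fd <- vapply(seq_len(nP), function(j) {
    up <- p; dn <- p
    up[j] <- up[j] + 1e-5
    dn[j] <- dn[j] - 1e-5
    (lossAt(up) - lossAt(dn)) / 2e-5
  }, numeric(1))
  expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-6)
})

test_that("ANN baselines have the documented sizes and null behavior", {
  # parameter count for one hidden layer of 10 on D inputs
  D <- 60L
  expect_equal(conveegnn:::.mlpCountParamsCpp(c(D, 10L, 2L), c(1L, 2L)),
               (D + 1) * 10 + 11 * 2)
  ep <- simulateEpochs(simConfig(nTrials = 24, noiseSigma = 3, seed = 50))
  spec <- classifierSpec("ann1", learningRate = 0, maxEpochs = 5,
                         patience = 5)
  ctx <- prepareContext(spec, ep, "pre")
  fit <- fitClassifier(spec, ctx, 1:16, seed = 1)
  preds <- predictClassifier(spec, fit, ctx, 17:24)
  expect_true(all(preds %in% c("remembered", "forgotten")))
  # untrained network is at chance on a large labeled set
  accs <- mean(predictClassifier(spec, fit, ctx, 1:24) == trialLabels(ep))
  expect_lt(abs(accs - 0.5), 0.35)
  spec2 <- classifierSpec("ann2")
  expect_equal(spec2@hidden, c(20L, 10L))
})

test_that("cubic SVM fits separable and curved boundaries", {
  set.seed(4)
  X <- rbind(matrix(rnorm(40, mean = 0, sd = 0.3), 20, 2),
             matrix(rnorm(40, mean = 2, sd = 0.3), 20, 2))
  lab <- rep(c("forgotten", "remembered"), each = 20)
  fit <- conveegnn:::fitCubicSVM(X, lab, costGrid = 1)
  expect_equal(as.character(predict(fit, X)), lab)   # separable: exact
  # XOR pattern: cubic kernel beats a linear margin
  n <- 60
  Xx <- matrix(runif(2 * n, -1, 1), n, 2)
  labx <- ifelse(Xx[, 1] * Xx[, 2] > 0, "remembered", "forgotten")
  cubic <- e1071::svm(Xx, factor(labx), kernel = "polynomial", degree = 3,
                      coef0 = 1, cost = 10)
  linear <- e1071::svm(Xx, factor(labx), kernel = "linear", cost = 10)
  accC <- mean(predict(cubic, Xx) == labx)
  accL <- mean(predict(linear, Xx) == labx)
  expect_gt(accC, accL)
  # determinism on identical input
  f1 <- conveegnn:::fitCubicSVM(X, lab, costGrid = 1)
  expect_identical(f1$coefs, fit$coefs)
  expect_identical(f1$rho, fit$rho)
})

test_that("CSP whitens the composite covariance into paired eigenvalues", {
  set.seed(5)
  n <- 40
  dat <- array(rnorm(n * 6 * 200), c(n, 6, 200))
  # class-dependent variance on a planted spatial pattern
  pat <- c(2, 1, 0, 0, -1, 1)
  for (i in 1:20)
    dat[i, , ] <- dat[i, , ] + outer(pat, rnorm(200, sd = 2))
  lab <- rep(c("remembered", "forgotten"), each = 20)
  csp <- cspFilters(dat, lab, nPairs = 2)
  expect_equal(dim(csp$filters), c(4, 6))
  # each filter's shares of the two trace-normalized class covariances sum
  # to one (whitening), and the remembered share matches the eigenvalues
  classCov <- function(idx) {
    S <- 0
    for (i in idx) {
      Xi <- dat[i, , ]
      Ci <- tcrossprod(Xi - rowMeans(Xi))
      S <- S + Ci / sum(diag(Ci))
    }
    S / length(idx)
  }
  C1 <- classCov(1:20)
  C0 <- classCov(21:40)
  d1 <- diag(csp$filters %*% C1 %*% t(csp$filters))
  d0 <- diag(csp$filters %*% C0 %*% t(csp$filters))
  expect_true(all(abs(d1 + d0 - 1) < 1e-8))
  expect_equal(unname(d1), csp$eigenvalues, tolerance = 1e-8)
  # top filter recovers variance concentrated in the planted pattern
  f1 <- csp$filters[1, ]
  v1 <- mean(vapply(1:20, function(i) var(as.numeric(f1 %*% dat[i, , ])),
                    numeric(1)))
  v0 <- mean(vapply(21:40, function(i) var(as.numeric(f1 %*% dat[i, , ])),
                    numeric(1)))
  expect_gt(v1 / v0, 3)
})

test_that("the fusion classifier follows unanimous branches", {
  ep <- simulateEpochs(simConfig(nTrials = 40, noiseSigma = 1.5,
                                 transientRate = 0, seed = 51))
  spec <- classifierSpec("svmlda")
  ctx <- prepareContext(spec, ep, "entire")
  fit <- fitClassifier(spec, ctx, 1:30, seed = 2)
  preds <- predictClassifier(spec, fit, ctx, 31:40)
  expect_true(all(preds %in% c("remembered", "forgotten")))
  # at this SNR the planted effect drives a clearly above-chance fusion
  expect_gte(mean(preds == trialLabels(ep)[31:40]), 0.7)
})

test_that("Morlet band power responds selectively in frequency", {
  fs <- 500
  t <- seq(0, 3 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 4 * t)
  p4 <- mean(morletPower(x, fs, 4))
  p11 <- mean(morletPower(x, fs, 11.26))
  expect_gt(p4 / p11, 50)
  # wavelet power localizes a burst in time
  burst <- ifelse(t > 1 & t < 1.5, sin(2 * pi * 6.42 * t), 0)
  pw <- morletPower(burst, fs, 6.42)
  expect_gt(mean(pw[t > 1.1 & t < 1.4]), 10 * mean(pw[t < 0.8]))
})

test_that("wavelet features flag the window carrying a planted burst", {
  set.seed(6)
  dat <- array(rnorm(20 * 6 * 1500, sd = 1), c(20, 6, 1500))
  tAx <- -0.1 + (0:1499) / 500
  burst <- ifelse(tAx >= 0.5 & tAx < 1.2, 6 * sin(2 * pi * 4 * tAx), 0)
  for (i in 1:10) dat[i, 1:2, ] <- dat[i, 1:2, ] + rep(burst, each = 2)
  ep <- makeEpochs(dat, rep(c("remembered", "forgotten"), each = 10),
                   channels = c("Fp1", "Fp2", "Cz", "Pz", "O1", "O2"))
  feat <- conveegnn:::cwtFeatureMatrix(ep)
  zs <- abs(colMeans(feat[1:10, ]) - colMeans(feat[11:20, ])) /
    apply(feat, 2, sd)
  expect_equal(names(which.max(zs)), "f4.00_pre_frontal")
})

test_that("the L1 wavelet classifier stays near chance without signal", {
  # a single finite dataset carries chance class structure shared by train
  # and test trials, so null calibration pools over data seeds
  nc <- 0L
  nt <- 0L
  for (s in 1:4) {
    ep <- simulateEpochs(simConfig(nTrials = 30, preEffect = 0,
                                   duringEffect = 0, thetaAmpDiff = 0,
                                   noiseSigma = 4, seed = 520 + s))
    cv <- crossValidate(ep, classifierSpec("cwtsvm"), "entire", seed = s)
    nc <- nc + cv@nCorrect
    nt <- nt + cv@nTotal
  }
  band <- qbinom(c(0.005, 0.995), nt, 0.5) / nt
  expect_gte(nc / nt, band[1])
  expect_lte(nc / nt, band[2])
})
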