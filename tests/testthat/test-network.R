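test_that("per-layer parameter counts follow the closed-form formulas", {
  cfg <- networkConfig(nCh = 30, tLen = 75, nC = 1, p = 3)
  pc <- countParams(cfg)
  expect_equal(pc$parameters$Lc, 31)       # N_c (M + 1)
  expect_equal(pc$parameters$Lcs, 26)      # K_1 + 1 = 25 + 1
  expect_equal(pc$parameters$Lh, 40)       # Q (sum P + 1)
  expect_equal(pc$parameters$Lout, 22)     # 2 (Q + 1)
  expect_equal(pc$connections$Lc, 75 * 31)
  expect_equal(pc$connections$Lcs, 3 * 26)
  # the flat parameter vector matches the counted total
  expect_equal(length(conveegnn:::flattenParams(initParams(cfg))), pc$total)
  expect_error(networkConfig(tLen = 75, nC = 1, p = 4), "divide")
})

test_that("initialization draws every weight within the 1/sqrt(n) bound", {
  cfg <- networkConfig(nCh = 30, tLen = 75, nC = 2, p = c(3, 5), seed = 1)
  pr <- initParams(cfg)
  expect_true(all(abs(pr@spatialKernels) <= 1 / sqrt(30)))
  expect_true(all(abs(pr@spatialBias) <= 1 / sqrt(30)))
  for (m in 1:2)
    expect_true(all(abs(pr@temporalKernels[[m]]) <=
                      1 / sqrt(length(pr@temporalKernels[[m]]))))
  expect_true(all(abs(pr@hiddenW) <= 1 / sqrt(8)))   # sum(P) = 8 inputs
  expect_true(all(abs(pr@outW) <= 1 / sqrt(10)))
  expect_identical(conveegnn:::flattenParams(initParams(cfg)),
                   conveegnn:::flattenParams(initParams(cfg)))
  # round trip through the flat layout
  expect_equal(conveegnn:::flattenParams(
    conveegnn:::unflattenParams(conveegnn:::flattenParams(pr), cfg)),
    conveegnn:::flattenParams(pr))
})

test_that("all-zero parameters give chance outputs and the tie rule", {
  cfg <- networkConfig(nCh = 4, tLen = 12, nC = 1, p = 3, seed = 1)
  pr <- initParams(cfg)
  zero <- conveegnn:::unflattenParams(
    numeric(length(conveegnn:::flattenParams(pr))), cfg)
  tr <- forwardPass(zero, cfg, matrix(rnorm(48), 4, 12))
  expect_equal(unname(tr$z), c(0.5, 0.5))
  expect_true(all(tr$xc == 0))
  expect_equal(predictLabel(zero, cfg, matrix(rnorm(48), 4, 12)),
               "remembered")
})

test_that("feedforward matches the naive triple-loop reference", {
  set.seed(42)
  for (rep in 1:60) {
    cfg <- randomSmallConfig()
    pr <- initParams(cfg)
    input <- matrix(rnorm(cfg@nCh * cfg@tLen), cfg@nCh, cfg@tLen)
    fast <- forwardPass(pr, cfg, input)
    ref <- naiveForward(pr, cfg, input)
    expect_equal(unname(fast$z), ref$z, tolerance = 1e-12)
    expect_equal(unname(fast$xc), ref$xc, tolerance = 1e-12)
    expect_equal(lapply(fast$xcs, unname), ref$xcs, tolerance = 1e-12)
  }
})

test_that("analytic gradients match central finite differences", {
  set.seed(7)
  cfg <- networkConfig(nCh = 4, tLen = 12, nC = 2, p = c(3, 4), seed = NA)
  for (rep in 1:5) {
    pr <- initParams(cfg)
    input <- matrix(rnorm(48), 4, 12)
    target <- if (rep %% 2) c(1, 0) else c(0, 1)
    bw <- backwardPass(pr, cfg, input, target)
    g <- conveegnn:::flattenParams(bw$gradient)
    ref <- finiteDiffGrad(pr, cfg, input, target)
    expect_lt(max(abs(g - ref)) / max(max(abs(ref)), 1e-8), 1e-6)
  }
})

test_that("gradient degenerate cases behave linearly", {
  cfg <- networkConfig(nCh = 3, tLen = 6, nC = 1, p = 2, seed = 3)
  pr <- initParams(cfg)
  input <- matrix(rnorm(18), 3, 6)
  z <- forwardPass(pr, cfg, input)$z
  # target equal to the outputs: all gradients vanish
  g0 <- conveegnn:::flattenParams(backwardPass(pr, cfg, input, z)$gradient)
  expect_true(all(abs(g0) < 1e-12))
  # gradient accumulation is additive over repeated presentations
  g1 <- conveegnn:::flattenParams(
    backwardPass(pr, cfg, input, c(1, 0))$gradient)
  expect_equal(2 * g1, g1 + g1)
})

test_that("spatial feature maps are covariant with input shifts", {
  cfg <- networkConfig(nCh = 5, tLen = 20, nC = 2, p = c(4, 5), seed = 9)
  pr <- initParams(cfg)
  input <- matrix(rnorm(100), 5, 20)
  shifted <- cbind(input[, -1], rnorm(5))   # delay by one sample
  xc1 <- forwardPass(pr, cfg, input)$xc
  xc2 <- forwardPass(pr, cfg, shifted)$xc
  expect_equal(unname(xc2[1:19, ]), unname(xc1[2:20, ]), tolerance = 1e-12)
})

test_that("activations stay within their analytic ranges", {
  cfg <- networkConfig(nCh = 6, tLen = 12, nC = 2, p = c(3, 4), seed = 4)
  pr <- initParams(cfg)
  input <- matrix(rnorm(72, sd = 50), 6, 12)   # large inputs
  tr <- forwardPass(pr, cfg, input)
  # open bound analytically; tanh saturates to +/-1 in floating point
  expect_true(all(abs(tr$xc) <= 1.7159))
  expect_true(all(abs(unlist(tr$xcs)) <= 1.7159))
  expect_true(all(tr$xh > 0 & tr$xh < 1))
  expect_true(all(tr$z > 0 & tr$z < 1))
})

test_that("weight sharing localizes single-sample perturbations", {
  cfg <- networkConfig(nCh = 4, tLen = 12, nC = 2, p = c(3, 4), seed = 5)
  pr <- initParams(cfg)
  input <- matrix(rnorm(48), 4, 12)
  base <- forwardPass(pr, cfg, input)
  pert <- input
  pert[2, 7] <- pert[2, 7] + 1
  new <- forwardPass(pr, cfg, pert)
  for (m in 1:2) {
    changedC <- which(abs(new$xc[, m] - base$xc[, m]) > 1e-12)
    expect_equal(changedC, 7L)               # exactly one spatial position
    changedCS <- which(abs(new$xcs[[m]] - base$xcs[[m]]) > 1e-12)
    expect_lte(length(changedCS), 1L)        # within one receptive field
  }
})

test_that("the decision rule maps output activations to labels", {
  # Z0 > Z1 -> forgotten, otherwise (including ties) remembered
  cfg <- networkConfig(nCh = 2, tLen = 4, nC = 1, p = 2, q = 1, seed = 6)
  pr <- initParams(cfg)
  # force outputs through the output bias with zero weights elsewhere
  pr@outW[] <- 0
  pr@outB <- c(2, -2)       # Z0 ~ 0.88, Z1 ~ 0.12
  x <- matrix(0, 2, 4)
  expect_equal(predictLabel(pr, cfg, x), "forgotten")
  pr@outB <- c(-2, 2)
  expect_equal(predictLabel(pr, cfg, x), "remembered")
  pr@outB <- c(0.3, 0.3)
  expect_equal(predictLabel(pr, cfg, x), "remembered")
})

test_that("class balancing duplicates the minority class cyclically", {
  labels <- c(rep("remembered", 10), rep("forgotten", 4))
  set.seed(1)
  sp <- conveegnn:::balancedSplit(labels, valFraction = 0)
  tab <- table(labels[sp$train])
  expect_equal(unname(tab[["remembered"]]), 10)
  expect_equal(unname(tab[["forgotten"]]), 10)
  # duplicated indices really are copies of minority trials
  expect_true(all(sp$train[labels[sp$train] == "forgotten"] %in% 11:14))
})

test_that("zero learning rate leaves the parameters unchanged", {
  ep <- simulateEpochs(quietCfg(nTrials = 12, noiseSigma = 1, seed = 13))
  mi <- prepareInput(ep, "pre")
  cfg <- networkConfig(nCh = 30, tLen = 30, nC = 1, p = 3,
                       learningRate = 0, maxEpochs = 5, patience = 5,
                       nRestarts = 1, seed = 77)
  fit <- trainNetwork(mi, cfg = cfg)
  expect_true(all(abs(diff(fit@history$trainMSE)) < 1e-12))
  expect_equal(fit@bestEpoch, 1L)
})

test_that("training separable data converges and tracks validation error", {
  ep <- simulateEpochs(simConfig(nTrials = 60, noiseSigma = 1.5, seed = 14))
  mi <- prepareInput(ep, "entire")
  cfg <- networkConfig(nC = 1, p = 3, seed = 15)
  fit <- trainNetwork(mi, cfg = cfg)
  preds <- predictLabel(fit, inputs = inputMatrices(mi))
  expect_gte(mean(preds == trialLabels(mi)), 0.9)
  # best epoch achieves the minimum recorded validation error
  expect_equal(fit@history$valMSE[fit@bestEpoch], min(fit@history$valMSE))
  # running minimum is non-increasing by construction
  expect_true(all(diff(cummin(fit@history$valMSE)) <= 0))
  expect_error(trainNetwork(inputMatrices(mi), rep("remembered", 60), cfg),
               "each class")
})

test_that("training is reproducible given the configuration seed", {
  ep <- simulateEpochs(simConfig(nTrials = 20, noiseSigma = 2, seed = 16))
  mi <- prepareInput(ep, "pre")
  cfg <- networkConfig(nCh = 30, tLen = 30, nC = 1, p = 3, maxEpochs = 30,
                       nRestarts = 2, seed = 99)
  f1 <- trainNetwork(mi, cfg = cfg)
  f2 <- trainNetwork(mi, cfg = cfg)
  expect_identical(conveegnn:::flattenParams(f1@params),
                   conveegnn:::flattenParams(f2@params))
})
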