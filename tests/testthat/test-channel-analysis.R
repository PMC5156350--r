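makeParams <- function(kernels) {
  cfg <- networkConfig(nCh = ncol(kernels), tLen = 6, nC = nrow(kernels),
                       p = rep(2L, nrow(kernels)), q = 2, seed = 1)
  pr <- initParams(cfg)
  pr@spatialKernels <- kernels
  pr
}

test_that("weight map scores are absolute, averaged, then range-scaled", {
  pr <- makeParams(matrix(c(0.5, -0.5, 0.1), 1, 3))
  map <- weightMap(pr, window = "pre", chNames = c("A", "B", "C"))
  expect_equal(unname(map@scores), c(1, 1, 0))
  # sign flips leave the map unchanged
  flipped <- makeParams(matrix(c(-0.5, 0.5, -0.1), 1, 3))
  map2 <- weightMap(flipped, window = "pre", chNames = c("A", "B", "C"))
  expect_equal(map@scores, map2@scores)
  # model order does not matter
  pr2 <- makeParams(matrix(c(0.2, 0.9, 0.4), 1, 3))
  m12 <- weightMap(list(pr, pr2), chNames = c("A", "B", "C"))
  m21 <- weightMap(list(pr2, pr), chNames = c("A", "B", "C"))
  expect_equal(m12@scores, m21@scores)
  # all-equal kernels degenerate to zero scores rather than dividing by zero
  flat <- makeParams(matrix(0.3, 1, 3))
  expect_equal(unname(weightMap(flat, chNames = c("A", "B", "C"))@scores),
               c(0, 0, 0))
})

test_that("top channels sort by score with montage-order tie breaks", {
  map <- new("ChannelWeightMap",
             scores = c(Fp1 = 1, F7 = 0.8, F8 = 0.8, Cz = 0.1, Pz = 0),
             window = "entire", nModels = 1L)
  expect_equal(topChannels(map, 3), c("Fp1", "F7", "F8"))
  expect_equal(topChannels(map, 5), c("Fp1", "F7", "F8", "Cz", "Pz"))
  expect_error(topChannels(map, 6), "exceeds")
  tied <- new("ChannelWeightMap", scores = c(B = 0.5, A = 0.5),
              window = "pre", nModels = 1L)
  expect_equal(topChannels(tied, 1), "B")   # first in montage order
})

test_that("grand averages weight participants equally", {
  mkP <- function(seed, nTrials = 20)
    simulateEpochs(simConfig(nTrials = nTrials, noiseSigma = 2,
                             transientRate = 0, seed = seed))
  ps <- lapply(1:4, mkP)
  rep1 <- grandAverageSME(ps)
  expect_equal(rep1@nParticipants, 4L)
  # duplicating one participant's trials changes nothing
  dup <- ps[[1]]
  dup@data <- dup@data[rep(1:20, 2), , ]
  dup@labels <- rep(dup@labels, 2)
  dup@trialIds <- seq_len(40)
  dup@movement <- rep(FALSE, 40)
  rep2 <- grandAverageSME(c(list(dup), ps[-1]))
  expect_equal(rep1@grandAverage$remembered, rep2@grandAverage$remembered,
               tolerance = 1e-12)
})

test_that("planted window effects appear in the SME report with the right polarity", {
  ps <- lapply(1:8, function(s)
    simulateEpochs(simConfig(nTrials = 40, noiseSigma = 2,
                             transientRate = 0, seed = 60 + s)))
  rep <- grandAverageSME(ps, channels = "Fp1")
  ws <- rep@windowStats
  pre <- ws[ws$window == "pre", ]
  dur <- ws[ws$window == "during", ]
  expect_lt(pre$difference, 0)              # negative-going when remembered
  expect_gt(dur$difference, 0)              # positive-going when remembered
  expect_equal(pre$difference, -2, tolerance = 0.5)
  expect_equal(dur$difference, 2, tolerance = 0.5)
  expect_lt(pre$p, 0.01)
  expect_lt(dur$p, 0.01)
})

test_that("degenerate inputs are reported as no-effect, not errors", {
  dat <- array(1, c(6, 3, 1500))
  ep <- makeEpochs(dat, rep(c("remembered", "forgotten"), 3),
                   channels = c("Fp1", "Cz", "Pz"))
  rep <- suppressWarnings(grandAverageSME(list(ep, ep), channels = "Fp1"))
  expect_equal(rep@windowStats$difference, c(0, 0))
  expect_true(all(is.na(rep@windowStats$t)))
  oneClass <- makeEpochs(dat, rep("remembered", 6),
                         channels = c("Fp1", "Cz", "Pz"))
  expect_warning(expect_error(grandAverageSME(list(oneClass)), "no participant"),
                 "lacks a class")
})

test_that("trained models concentrate weight on the planted channels", {
  ep <- simulateEpochs(simConfig(nTrials = 80, noiseSigma = 2,
                                 transientRate = 0, seed = 70))
  mi <- prepareInput(ep, "entire")
  cfg <- networkConfig(nC = 1, p = 3, maxEpochs = 200, nRestarts = 2,
                       seed = 71)
  fit <- trainNetwork(mi, cfg = cfg)
  map <- weightMap(fit, window = "entire", chNames = channelNames(mi))
  planted <- c("Fp1", "Fp2", "F7", "F8", "F3")
  expect_gt(length(intersect(topChannels(map, 3), planted)), 0)
})
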