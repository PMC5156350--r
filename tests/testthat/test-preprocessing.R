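test_that("linked-mastoid re-referencing subtracts the mastoid mean", {
  m <- tinyMontage()
  sig <- matrix(1, 6, 100)
  sig[3, ] <- 4   # TP9
  sig[4, ] <- 6   # TP10
  ses <- makeSession(sig, m)
  out <- reReference(ses)
  # every non-EOG channel shifted by -(4+6)/2 = -5
  expect_equal(out@signal["Fp1", ], rep(1 - 5, 100))
  expect_equal(out@signal["Cz", ], rep(-4, 100))
  # EOG channels untouched
  expect_equal(out@signal["VEOG", ], rep(1, 100))
  # zero mastoids leave the signal unchanged
  sig0 <- matrix(rnorm(600), 6, 100)
  sig0[3:4, ] <- 0
  expect_equal(reReference(makeSession(sig0, m))@signal, {
    s <- sig0
    rownames(s) <- m@channelNames
    s
  })
  expect_error(reReference(makeSession(sig, montage(m@channelNames,
    eogChannels = c("VEOG", "HEOG")))), "mastoid")
})

test_that("band-pass is zero-phase with the specified roll-off", {
  fs <- 500
  t <- seq(0, 8 - 1 / fs, by = 1 / fs)
  m <- tinyMontage()
  # amplitude response via sinusoid probes
  probe <- function(f) {
    x <- sin(2 * pi * f * t)
    ses <- makeSession(matrix(x, 6, length(t), byrow = TRUE), m)
    y <- bandpassFilter(ses)@signal[1, ]
    core <- seq(2 * fs, 6 * fs)  # avoid edges
    sqrt(mean(y[core]^2)) / sqrt(mean(x[core]^2))
  }
  expect_lt(20 * log10(probe(50)), -40)     # stop band
  expect_gt(probe(5), 0.95)                 # pass band within 5%
  # DC removal
  dc <- makeSession(matrix(100, 6, length(t)), m)
  expect_lt(max(abs(bandpassFilter(dc)@signal)), 1e-6)
  # zero phase: impulse peak latency preserved
  imp <- matrix(0, 6, length(t))
  imp[, 2000] <- 1
  y <- bandpassFilter(makeSession(imp, m))@signal[2, ]
  expect_lt(abs(which.max(y) - 2000), 2)
  # time-reversal symmetry (exact zero-phase realization)
  x <- rnorm(3000)
  s1 <- bandpassFilter(makeSession(matrix(x, 6, 3000, byrow = TRUE), m))
  s2 <- bandpassFilter(makeSession(matrix(rev(x), 6, 3000, byrow = TRUE), m))
  a <- s1@signal[1, ]
  b <- rev(s2@signal[1, ])
  expect_lt(max(abs(a - b)) / max(abs(a)), 1e-8)
  expect_error(bandpassFilter(s1, low = 20, high = 10), "band edges")
})

test_that("EOG regression removes propagated blink activity", {
  set.seed(7)
  fs <- 500
  n <- 20000
  m <- tinyMontage()
  veog <- conveegnn:::onefNoise(n, 1, 30)
  heog <- conveegnn:::onefNoise(n, 1, 15)
  sig <- matrix(rnorm(6 * n, sd = 3), 6, n)
  sig[1, ] <- sig[1, ] + 0.3 * veog          # Fp1 contaminated
  sig[2, ] <- sig[2, ] + 0.1 * heog          # Cz lightly contaminated
  sig[5, ] <- veog
  sig[6, ] <- heog
  ses <- regressEOG(makeSession(sig, m))
  expect_lt(abs(cor(ses@signal["Fp1", ], veog)), 0.1)
  expect_lt(abs(cor(ses@signal["Cz", ], heog)), 0.1)
  # recovered propagation factors
  b <- attr(ses, "eogCoefficients")
  expect_equal(unname(b["VEOG", "Fp1"]), 0.3, tolerance = 0.05)
  # channel orthogonal to both EOGs is essentially unchanged
  expect_equal(ses@signal["TP9", ], sig[3, ], tolerance = 0.05)
  # flat EOG: skipped with a warning, signal unchanged
  sigF <- sig
  sigF[5, ] <- 0
  sigF[6, ] <- 0
  expect_warning(out <- regressEOG(makeSession(sigF, m)), "flat")
  expect_equal(unname(out@signal["Fp1", ]), unname(sigF[1, ]))
})

test_that("segmentation uses half-open epochs time-locked to the cue", {
  m <- tinyMontage()
  fs <- 500
  sig <- matrix(seq_len(6 * 3000), 6, 3000)  # distinguishable samples
  ses <- makeSession(sig, m, nTrials = 0)
  ses@events <- data.frame(trial_id = 1L,
                           onset_sample = c(1000L, 1000L + 750L),
                           kind = c("cue", "word"))
  ses@responses <- data.frame(trial_id = 1L, key = 2)
  ses@annotations <- data.frame(trial_id = 1L, movement = FALSE)
  ep <- segmentEpochs(ses)
  expect_equal(dim(ep@data), c(1, 4, 1500))      # EOG dropped
  # epoch covers samples [950, 2450)
  expect_equal(unname(ep@data[1, 1, 1]), sig[1, 950])
  expect_equal(unname(ep@data[1, 1, 1500]), sig[1, 2449])
  expect_equal(trialLabels(ep), "remembered")
  # zero trials: empty epoch set, no error
  empty <- segmentEpochs(makeSession(sig, m, nTrials = 0))
  expect_equal(nTrials(empty), 0)
  # trial truncated at the recording edge is logged, not an error
  ses2 <- ses
  ses2@events$onset_sample <- c(10L, 760L)
  ep2 <- segmentEpochs(ses2)
  expect_equal(nTrials(ep2), 0)
  expect_equal(ep2@rejected$reason, "edge")
})

test_that("baseline correction zeroes the pre-cue window", {
  dat <- array(10, c(2, 3, 1500))
  dat[2, , ] <- 2
  dat[2, , 51:1500] <- 5
  ep <- baselineCorrect(makeEpochs(dat, c("remembered", "forgotten")))
  expect_true(all(ep@data[1, , ] == 0))         # constant trial becomes zero
  base <- apply(ep@data[, , 1:50, drop = FALSE], c(1, 2), mean)
  expect_true(all(abs(base) < 1e-12))
  expect_equal(ep@data[2, 1, 100], 3)           # 5 - 2
  late <- makeEpochs(dat, c("remembered", "forgotten"), tStart = 0)
  expect_error(baselineCorrect(late), "baseline")
})

test_that("artifact rejection drops exactly the constructed trials", {
  set.seed(1)
  dat <- array(rnorm(10 * 3 * 100, sd = 5), c(10, 3, 100))
  dat[2, 1, 50] <- 51
  dat[5, 2, 10] <- -51
  dat[7, 3, 99] <- 80
  dat[3, 1, 1] <- 50                             # exactly at threshold
  mov <- rep(FALSE, 10)
  mov[9] <- TRUE
  ep <- makeEpochs(dat, rep(c("remembered", "forgotten"), 5),
                   movement = mov)
  out <- rejectArtifacts(ep)
  expect_equal(nTrials(out), 6)
  expect_setequal(out@rejected$trial_id, c(2, 5, 7, 9))
  expect_equal(sort(out@rejected$reason), sort(c(rep("amplitude", 3),
                                                 "movement")))
  expect_true(3 %in% trialIds(out))              # boundary 50 retained
  # retained trials are bit-identical
  keep <- setdiff(1:10, c(2, 5, 7, 9))
  expect_identical(out@data, ep@data[keep, , , drop = FALSE])
})

test_that("input preparation yields the documented shapes and scaling", {
  ep <- simulateEpochs(simConfig(nTrials = 12, noiseSigma = 3, seed = 8))
  for (w in c(entire = 75L, pre = 30L, during = 30L)) NULL
  shapes <- c(entire = 75L, pre = 30L, during = 30L)
  for (w in names(shapes)) {
    mi <- prepareInput(ep, w)
    expect_equal(dim(epochData(mi)), c(12L, 30L, shapes[[w]]))
  }
  mi <- prepareInput(ep, "entire")
  pooledMean <- apply(mi@data, 2, mean)
  pooledVar <- apply(mi@data, 2, function(x) mean((x - mean(x))^2) *
                       length(x) / (length(x) - 1))
  expect_true(all(abs(pooledMean) < 1e-10))
  expect_true(all(abs(pooledVar - 1) < 1e-6))
})

test_that("supplied normalization statistics are echoed, never recomputed", {
  ep <- simulateEpochs(simConfig(nTrials = 10, noiseSigma = 3, seed = 9))
  trainEp <- makeEpochs(ep@data[1:6, , , drop = FALSE], trialLabels(ep)[1:6],
                        channels = channelNames(ep))
  testEp <- makeEpochs(ep@data[7:10, , , drop = FALSE], trialLabels(ep)[7:10],
                       channels = channelNames(ep))
  trainIn <- prepareInput(trainEp, "entire")
  st <- inputStats(trainIn)
  testIn <- prepareInput(testEp, "entire", stats = st)
  expect_identical(inputStats(testIn), st)
  # held-out trials scaled with the training stats are not re-centered
  expect_gt(max(abs(apply(testIn@data, 2, mean))), 1e-6)
})

test_that("naive decimation picks every factor-th raw sample", {
  dat <- array(rnorm(2 * 3 * 1500), c(2, 3, 1500))
  ep <- makeEpochs(dat, c("remembered", "forgotten"))
  dec <- conveegnn:::decimateEpochs(ep, 25, naive = TRUE)
  expect_equal(dec@data[1, 1, ], dat[1, 1, seq(1, 1500, by = 20)])
  # anti-aliased path differs from plain picking but keeps slow content
  dec2 <- conveegnn:::decimateEpochs(ep, 25, naive = FALSE)
  expect_false(isTRUE(all.equal(dec2@data, dec@data)))
})

test_that("each preprocessing step stamps its provenance", {
  ses <- simulateSession(simConfig(nTrials = 4, noiseSigma = 2, seed = 10))
  ep <- preprocessSession(ses)
  expect_true(all(c("rereference", "segment", "baseline") %in%
                    sub("\\[.*", "", ep@provenance)))
})
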