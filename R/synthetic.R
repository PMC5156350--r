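#' Configure the synthetic session generator
#'
#' Builds a [SimConfig-class] describing a synthetic auditory study-phase
#' session: cue at 0 s, word at 1.5 s, epochs spanning [-0.1, 2.9) s, trials
#' tiled sequentially with a short gap (response pause plus the fixed 0.6 s
#' inter-stimulus interval). The subsequent-memory effect is emulated as a
#' sustained negative-going shift over the pre-stimulus window [0.3, 1.5) s
#' and a sustained positive-going shift over the during-stimulus window
#' [1.5, 2.7) s, both on a frontal channel group for remembered trials only,
#' plus a theta-amplitude increment. Background activity is 1/f^alpha noise
#' plus white noise; blinks are mirrored on VEOG with a frontal-to-posterior
#' attenuation profile; a fixed fraction of trials carries a slow drift
#' exceeding the +/-50 uV rejection threshold.
#'
#' The default amplitudes were calibrated once so that, at 100 trials, the
#' planted effects are recoverable but not trivially separable (ridge LDA on
#' the entire-window input scores roughly 55-65 percent).
#'
#' @param nTrials number of trials.
#' @param pRemembered probability a trial is remembered.
#' @param samplingRate Hz.
#' @param effectChannels channels carrying the class effect (frontal group).
#' @param preEffect,duringEffect class-difference amplitudes in uV.
#' @param thetaFreq,thetaAmp,thetaAmpDiff theta parameters.
#' @param noiseSigma,whiteSigma,oneOverFExponent background noise parameters.
#' @param blinkRate,blinkAmp blink process parameters.
#' @param transientRate,transientAmp rate (events/s) and peak amplitude cap
#'   (uV) of sub-threshold spatially coherent transients: brief bumps with a
#'   random topography shared across channels, emulating residual muscle and
#'   electrode artifacts that stay under the rejection threshold.
#' @param driftTrialFraction,driftAmp drift-artifact parameters.
#' @param itiGap seconds from epoch end to the next cue.
#' @param seed integer seed.
#' @return a [SimConfig-class].
#' @export
#' @examples
#' cfg <- simConfig(nTrials = 10, seed = 1)
#' ses <- simulateSession(cfg)
#' ses
simConfig <- function(nTrials = 100L, pRemembered = 0.5, samplingRate = 500,
                      effectChannels = c("Fp1", "Fp2", "F7", "F8", "F3"),
                      preEffect = -2, duringEffect = 2,
                      thetaFreq = 5, thetaAmp = 2, thetaAmpDiff = 1,
                      noiseSigma = 9, whiteSigma = 1, oneOverFExponent = 1,
                      blinkRate = 0.1, blinkAmp = 100,
                      transientRate = 0.7, transientAmp = 32,
                      driftTrialFraction = 0.05, driftAmp = 100,
                      itiGap = 0.7, seed = 1L) {
  new("SimConfig",
      nTrials = as.integer(nTrials), pRemembered = pRemembered,
      samplingRate = samplingRate, cueTime = 0, wordTime = 1.5,
      trialSpan = c(-0.1, 2.9), itiGap = itiGap,
      effectChannels = effectChannels,
      preWindow = c(0.3, 1.5), duringWindow = c(1.5, 2.7),
      preEffect = preEffect, duringEffect = duringEffect,
      thetaFreq = thetaFreq, thetaAmp = thetaAmp, thetaAmpDiff = thetaAmpDiff,
      noiseSigma = noiseSigma, whiteSigma = whiteSigma,
      oneOverFExponent = oneOverFExponent,
      blinkRate = blinkRate, blinkAmp = blinkAmp,
      transientRate = transientRate, transientAmp = transientAmp,
      driftTrialFraction = driftTrialFraction, driftAmp = driftAmp,
      seed = as.integer(seed))
}

# brief spatially coherent bump added to a channels x samples block:
# random topography (peak 1), random center/width/sign, amplitude in
# [0.4, 1] x cap; zero-mean over trials and classes by construction
addTransient <- function(block, tAx, cap) {
  ctr <- stats::runif(1, min(tAx), max(tAx))
  wid <- stats::runif(1, 0.05, 0.15)
  amp <- cap * stats::runif(1, 0.4, 1) * sample(c(-1, 1), 1L)
  topo <- stats::rnorm(nrow(block))
  topo <- topo / max(abs(topo))
  block + outer(topo, amp * exp(-(tAx - ctr)^2 / (2 * wid^2)))
}

# 1/f^alpha Gaussian noise by frequency-domain synthesis, standardized to sd.
onefNoise <- function(n, alpha, sd) {
  if (sd == 0 || n < 4L) return(numeric(n))
  nf <- (n - 1L) %/% 2L
  amp <- (1:nf)^(-alpha / 2)
  ph <- stats::runif(nf, 0, 2 * pi)
  half <- amp * exp(1i * ph)
  spec <- if (n %% 2L == 0L) c(0, half, stats::rnorm(1), Conj(rev(half)))
          else c(0, half, Conj(rev(half)))
  x <- Re(stats::fft(spec, inverse = TRUE))
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x / s * sd
}

gaussBump <- function(t, lat, width, amp) amp * exp(-(t - lat)^2 / (2 * width^2))

# Evoked template shared by both classes: cue components then word components,
# as sums of Gaussian-windowed deflections (t in seconds relative to cue).
erpTemplate <- function(t) {
  gaussBump(t, 0.10, 0.04, -3) + gaussBump(t, 0.25, 0.08, 4) +
    gaussBump(t, 1.60, 0.05, -4) + gaussBump(t, 1.75, 0.08, 5) +
    gaussBump(t, 2.10, 0.20, 3)
}

# anterior-posterior row index per 10/10 label (1 = frontopolar ... 7 = occipital)
channelRow <- function(names) {
  row <- integer(length(names))
  pats <- list("^Fp" = 1L, "^AF" = 2L, "^F[0-9z]" = 2L, "^F[78]" = 2L,
               "^FC" = 3L, "^FT" = 3L, "^[CT][0-9z]" = 4L, "^T[78]" = 4L,
               "^CP" = 5L, "^TP" = 5L, "^P[0-9z]" = 6L, "^PO" = 6L,
               "^O" = 7L, "^I" = 7L)
  for (p in names(pats)) row[grepl(p, names) & row == 0L] <- pats[[p]]
  row[row == 0L] <- 4L
  row
}

# blink propagation factor per channel (frontal high, posterior low)
blinkAttenuation <- function(names) {
  c(0.35, 0.25, 0.18, 0.12, 0.08, 0.05, 0.03)[channelRow(names)]
}

# evoked-response topography (frontal-weighted, never zero)
erpTopography <- function(names) {
  1 - 0.08 * (channelRow(names) - 1L)
}

#' Simulate a continuous study-phase recording
#'
#' Generates a continuous multichannel recording with per-trial additive
#' structure (background noise, cue and word evoked responses, class-dependent
#' window shifts, theta oscillation, blinks mirrored on VEOG, drift trials),
#' plus event, response and annotation tables. Deterministic given
#' \code{cfg@seed}.
#'
#' @param cfg a [SimConfig-class].
#' @param mont a [Montage-class]; default [defaultMontage()].
#' @return a [RawSession-class] with \code{truthLabels} populated.
#' @export
simulateSession <- function(cfg, mont = defaultMontage()) {
  validObject(cfg)
  if (!all(cfg@effectChannels %in% mont@channelNames))
    stop("effectChannels not present in montage: ",
         paste(setdiff(cfg@effectChannels, mont@channelNames), collapse = ", "))
  if (cfg@itiGap < 0)
    stop("itiGap < 0: consecutive trial epochs would overlap")
  withSeed(cfg@seed, .simulateSessionImpl(cfg, mont))
}

.simulateSessionImpl <- function(cfg, mont) {
  fs <- cfg@samplingRate
  n <- cfg@nTrials
  span <- cfg@trialSpan
  period <- diff(span) + cfg@itiGap
  lead <- 0.5
  cueTimes <- lead - span[1L] + period * (seq_len(n) - 1L)
  total <- lead - span[1L] + period * (n - 1L) + span[2L] + 0.5
  ns <- ceiling(total * fs)
  chn <- mont@channelNames
  nch <- length(chn)
  scalp <- setdiff(chn, mont@eogChannels)

  labels <- ifelse(stats::runif(n) < cfg@pRemembered, "remembered", "forgotten")

  sig <- matrix(0, nch, ns, dimnames = list(chn, NULL))
  # background: 1/f + white on scalp channels, lighter noise on EOG channels
  for (ch in seq_len(nch)) {
    sdc <- if (chn[ch] %in% mont@eogChannels) cfg@noiseSigma / 2 else cfg@noiseSigma
    sig[ch, ] <- onefNoise(ns, cfg@oneOverFExponent, sdc) +
      stats::rnorm(ns, 0, cfg@whiteSigma)
  }

  topo <- erpTopography(chn)
  topo[chn %in% mont@eogChannels] <- 0
  effIdx <- match(cfg@effectChannels, chn)
  epLen <- round(diff(span) * fs)
  relT <- (seq_len(epLen) - 1L) / fs + span[1L]
  template <- erpTemplate(relT)
  preMask <- relT >= cfg@preWindow[1L] & relT < cfg@preWindow[2L]
  durMask <- relT >= cfg@duringWindow[1L] & relT < cfg@duringWindow[2L]

  nDrift <- round(cfg@driftTrialFraction * n)
  driftTrials <- if (nDrift > 0L) sample.int(n, nDrift) else integer(0)

  for (i in seq_len(n)) {
    s0 <- round((cueTimes[i] + span[1L]) * fs)   # 0-based epoch start
    idx <- s0 + seq_len(epLen)
    rem <- labels[i] == "remembered"
    # evoked template with frontal-weighted topography
    sig[, idx] <- sig[, idx] + outer(topo, template)
    # class-dependent sustained shifts on the effect channels
    if (rem) {
      add <- cfg@preEffect * preMask + cfg@duringEffect * durMask
      sig[effIdx, idx] <- sig[effIdx, idx] + rep(add, each = length(effIdx))
    }
    # theta oscillation: base on all scalp channels, increment on effect
    # channels for remembered trials; random phase per trial
    ph <- stats::runif(1, 0, 2 * pi)
    theta <- sin(2 * pi * cfg@thetaFreq * (relT - span[1L]) + ph)
    sig[match(scalp, chn), idx] <- sig[match(scalp, chn), idx] +
      rep(cfg@thetaAmp * theta, each = length(scalp))
    if (rem && cfg@thetaAmpDiff != 0)
      sig[effIdx, idx] <- sig[effIdx, idx] +
        rep(cfg@thetaAmpDiff * theta, each = length(effIdx))
    # sub-threshold coherent transients (residual artifacts), on the scalp
    # channels only so EOG regression is not confounded
    if (cfg@transientRate > 0) {
      nTr <- stats::rpois(1L, cfg@transientRate * diff(span))
      scalpIdx <- match(scalp, chn)
      for (j in seq_len(nTr))
        sig[scalpIdx, idx] <- addTransient(sig[scalpIdx, idx, drop = FALSE],
                                           relT, cfg@transientAmp)
    }
    # drift artifact: slow ramp exceeding the rejection threshold
    if (i %in% driftTrials) {
      ch <- sample(match(scalp, chn), 1L)
      sig[ch, idx] <- sig[ch, idx] +
        sample(c(-1, 1), 1L) * cfg@driftAmp * seq(0, 1, length.out = epLen)
    }
  }

  # blinks: Poisson events on VEOG, propagated with per-channel attenuation
  if (cfg@blinkRate > 0 && "VEOG" %in% chn) {
    nBlink <- stats::rpois(1L, cfg@blinkRate * total)
    if (nBlink > 0L) {
      att <- blinkAttenuation(chn)
      att[chn == "VEOG"] <- 1
      att[chn == "HEOG"] <- 0.1
      tAll <- (seq_len(ns) - 1L) / fs
      for (bt in stats::runif(nBlink, 0, total)) {
        w <- which(abs(tAll - bt) < 0.5)
        bump <- cfg@blinkAmp * exp(-(tAll[w] - bt)^2 / (2 * 0.08^2))
        sig[, w] <- sig[, w] + outer(att, bump)
      }
    }
  }
  # occasional horizontal saccades on HEOG with light frontal propagation
  if (cfg@blinkRate > 0 && "HEOG" %in% chn) {
    nSac <- stats::rpois(1L, 0.5 * cfg@blinkRate * total)
    if (nSac > 0L) {
      attH <- 0.05 * (channelRow(chn) <= 2L)
      attH[chn == "HEOG"] <- 1
      attH[chn == "VEOG"] <- 0.1
      tAll <- (seq_len(ns) - 1L) / fs
      for (st in stats::runif(nSac, 0, total)) {
        w <- which(abs(tAll - st) < 0.6)
        bump <- 0.4 * cfg@blinkAmp * exp(-(tAll[w] - st)^2 / (2 * 0.15^2))
        sig[, w] <- sig[, w] + outer(attH, bump)
      }
    }
  }

  cueSamp <- as.integer(round(cueTimes * fs)) + 1L
  wordSamp <- cueSamp + as.integer(round(1.5 * fs))
  ev <- data.frame(
    trial_id = rep(seq_len(n), each = 2L),
    onset_sample = as.vector(rbind(cueSamp, wordSamp)),
    kind = rep(c("cue", "word"), n),
    stringsAsFactors = FALSE)
  keys <- ifelse(labels == "remembered",
                 sample(1:2, n, replace = TRUE),
                 sample(3:5, n, replace = TRUE))
  resp <- data.frame(trial_id = seq_len(n), key = keys)
  ann <- data.frame(trial_id = seq_len(n), movement = FALSE)

  new("RawSession", signal = sig, samplingRate = fs, events = ev,
      responses = resp, annotations = ann, montage = mont,
      truthLabels = labels, provenance = "simulated")
}

#' Simulate clean, labeled epochs directly
#'
#' Fast path for unit tests: emits segmented, baseline-corrected, artifact-free
#' epochs on the non-EOG channels, equivalent to running the full
#' preprocessing chain on a blink- and drift-free session (no filtering is
#' needed because no out-of-band artifact is generated).
#'
#' @param cfg a [SimConfig-class].
#' @param mont a [Montage-class].
#' @return an [EpochSet-class] with \code{nTrials} trials, the montage's
#'   non-EOG channels, and samples spanning \code{cfg@trialSpan} at
#'   \code{cfg@samplingRate}.
#' @export
#' @examples
#' ep <- simulateEpochs(simConfig(nTrials = 10, seed = 2))
#' dim(epochData(ep))   # 10 x 30 x 1500
simulateEpochs <- function(cfg, mont = defaultMontage()) {
  validObject(cfg)
  if (!all(cfg@effectChannels %in% mont@channelNames))
    stop("effectChannels not present in montage")
  withSeed(cfg@seed, .simulateEpochsImpl(cfg, mont))
}

.simulateEpochsImpl <- function(cfg, mont) {
  fs <- cfg@samplingRate
  n <- cfg@nTrials
  span <- cfg@trialSpan
  epLen <- round(diff(span) * fs)
  chn <- eegChannels(mont)
  nch <- length(chn)
  relT <- (seq_len(epLen) - 1L) / fs + span[1L]
  template <- erpTemplate(relT)
  topo <- erpTopography(chn)
  preMask <- relT >= cfg@preWindow[1L] & relT < cfg@preWindow[2L]
  durMask <- relT >= cfg@duringWindow[1L] & relT < cfg@duringWindow[2L]
  effIdx <- match(intersect(cfg@effectChannels, chn), chn)

  labels <- ifelse(stats::runif(n) < cfg@pRemembered, "remembered", "forgotten")
  dat <- array(0, c(n, nch, epLen), dimnames = list(NULL, chn, NULL))
  for (i in seq_len(n)) {
    tr <- outer(topo, template)
    for (ch in seq_len(nch))
      tr[ch, ] <- tr[ch, ] + onefNoise(epLen, cfg@oneOverFExponent,
                                       cfg@noiseSigma) +
        stats::rnorm(epLen, 0, cfg@whiteSigma)
    ph <- stats::runif(1, 0, 2 * pi)
    theta <- sin(2 * pi * cfg@thetaFreq * (relT - span[1L]) + ph)
    tr <- tr + rep(cfg@thetaAmp * theta, each = nch)
    if (labels[i] == "remembered") {
      add <- cfg@preEffect * preMask + cfg@duringEffect * durMask +
        cfg@thetaAmpDiff * theta
      tr[effIdx, ] <- tr[effIdx, ] + rep(add, each = length(effIdx))
    }
    if (cfg@transientRate > 0) {
      nTr <- stats::rpois(1L, cfg@transientRate * diff(span))
      for (j in seq_len(nTr))
        tr <- addTransient(tr, relT, cfg@transientAmp)
    }
    # baseline correction over [-0.1, 0)
    base <- rowMeans(tr[, relT < 0, drop = FALSE])
    dat[i, , ] <- tr - base
  }
  new("EpochSet", data = dat, samplingRate = fs, tStart = span[1L],
      channelNames = chn, labels = labels, trialIds = seq_len(n),
      movement = rep(FALSE, n),
      rejected = data.frame(trial_id = integer(), reason = character()),
      provenance = c("simulated", "segment", "baseline"))
}
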