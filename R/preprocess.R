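# Preprocessing chain: re-reference -> band-pass -> EOG regression ->
# segmentation -> baseline correction -> artifact rejection -> input
# normalization. Each step returns a new object carrying a provenance tag.

#' Re-reference to linked mastoids
#'
#' Subtracts the arithmetic mean of the mastoid channels from every non-EOG
#' channel, sample-wise.
#'
#' @param session a [RawSession-class] whose montage names mastoid channels.
#' @return the re-referenced [RawSession-class].
#' @export
reReference <- function(session) {
  m <- session@montage
  if (length(m@mastoidChannels) == 0L)
    stop("montage declares no mastoid channels")
  if (!all(m@mastoidChannels %in% rownames(session@signal)))
    stop("mastoid channels absent from the recording")
  ref <- colMeans(session@signal[m@mastoidChannels, , drop = FALSE])
  eeg <- setdiff(m@channelNames, m@eogChannels)
  session@signal[eeg, ] <- sweep(session@signal[eeg, , drop = FALSE], 2L, ref)
  stampProvenance(session, "rereference")
}

# Zero-phase band-pass gain: squared magnitude of an order-4 Butterworth
# high-pass cascaded with an order-4 Butterworth low-pass (the forward plus
# backward pass of each doubles the effective roll-off to ~48 dB/octave).
butterGain <- function(f, low, high, orderLow = 4L, orderHigh = 4L) {
  g <- rep(1, length(f))
  if (!is.null(high)) g <- g / (1 + (f / high)^(2 * orderLow))
  if (!is.null(low)) {
    g <- g / (1 + ifelse(f > 0, (low / f)^(2 * orderHigh), Inf))
    g[f == 0] <- 0
  }
  g
}

# padded length n + 2L with small prime factors and matching parity
goodPaddedLength <- function(n, minPad) {
  np <- stats::nextn(n + 2L * minPad, c(2L, 3L, 5L))
  while ((np - n) %% 2L != 0L) np <- stats::nextn(np + 1L, c(2L, 3L, 5L))
  np
}

# Exactly zero-phase filtering: even-reflection padding, FFT, multiply by the
# real symmetric gain, inverse FFT, trim. Commutes exactly with time reversal.
zeroPhaseApply <- function(x, fs, gainFun, minPadSec = 10) {
  n <- length(x)
  np <- goodPaddedLength(n, min(n - 1L, round(minPadSec * fs)))
  padL <- (np - n) %/% 2L
  padRight <- np - n - padL
  left <- if (padL > 0L) x[pmin(n, 1L + (padL:1L))] else numeric(0)
  right <- if (padRight > 0L) x[pmax(1L, n - (1:padRight))] else numeric(0)
  xp <- c(left, x, right)
  f <- c(0:(np %/% 2L), -((np - np %/% 2L - 1L):1L)) * fs / np
  g <- gainFun(abs(f))
  y <- Re(stats::fft(stats::fft(xp) * g, inverse = TRUE)) / np
  y[padL + seq_len(n)]
}

#' Zero-phase band-pass filter
#'
#' Applies a zero-phase Butterworth band-pass (default 0.05-15 Hz, roll-off
#' about 48 dB/octave on each edge counting both passes) to every channel.
#' The filter is realized spectrally as the squared magnitude response of the
#' forward-backward cascade, so the phase shift is exactly zero and an
#' impulse keeps its peak latency.
#'
#' @param session a [RawSession-class].
#' @param low,high band edges in Hz.
#' @return the filtered [RawSession-class].
#' @export
bandpassFilter <- function(session, low = 0.05, high = 15) {
  fs <- session@samplingRate
  if (!(low > 0 && low < high && high < fs / 2))
    stop("band edges must satisfy 0 < low < high < samplingRate/2")
  gain <- function(f) butterGain(f, low, high)
  for (ch in seq_len(nrow(session@signal)))
    session@signal[ch, ] <- zeroPhaseApply(session@signal[ch, ], fs, gain)
  stampProvenance(session, sprintf("bandpass[%g-%g]", low, high))
}

#' Regress eye-movement artifacts out of the EEG channels
#'
#' Estimates per-channel propagation factors of VEOG and HEOG by ordinary
#' least squares over the whole continuous recording and subtracts the fitted
#' EOG contribution from every non-EOG channel. The EOG channels themselves
#' are left untouched. A flat (zero-variance) EOG channel is skipped with a
#' warning.
#'
#' @param session a [RawSession-class] whose montage names the EOG channels.
#' @return the corrected [RawSession-class]; the propagation factors are kept
#'   in \code{attr(, "eogCoefficients")}.
#' @export
regressEOG <- function(session) {
  m <- session@montage
  eog <- m@eogChannels
  if (length(eog) == 0L) stop("montage declares no EOG channels")
  E <- t(session@signal[eog, , drop = FALSE])
  keep <- apply(E, 2L, stats::sd) > 1e-12
  if (!any(keep)) {
    warning("all EOG channels are flat; recording unchanged")
    return(stampProvenance(session, "eog-regression[skipped]"))
  }
  if (!all(keep))
    warning("flat EOG channel skipped: ", paste(eog[!keep], collapse = ", "))
  E <- E[, keep, drop = FALSE]
  Ec <- sweep(E, 2L, colMeans(E))
  eeg <- setdiff(m@channelNames, eog)
  # least-squares propagation factors, all EEG channels at once
  b <- solve(crossprod(Ec), crossprod(Ec, t(session@signal[eeg, , drop = FALSE])))
  session@signal[eeg, ] <- session@signal[eeg, , drop = FALSE] -
    t(Ec %*% b)
  coefs <- matrix(0, length(eog), length(eeg),
                  dimnames = list(eog, eeg))
  coefs[keep, ] <- b
  attr(session, "eogCoefficients") <- coefs
  stampProvenance(session, "eog-regression")
}

#' Map memory-test key presses to trial labels
#'
#' Keys 1 (definitely familiar) and 2 (possibly familiar) label a studied
#' trial as remembered; keys 3-5 (uncertain through definitely unfamiliar)
#' label it as forgotten.
#'
#' @param responses data.frame with columns \code{trial_id} and \code{key}.
#' @return named character vector of labels, names = trial ids.
#' @export
#' @examples
#' labelTrials(data.frame(trial_id = 1:3, key = c(2, 3, 1)))
labelTrials <- function(responses) {
  key <- responses$key
  if (any(!key %in% 1:5))
    stop("response keys must be in 1..5")
  stats::setNames(ifelse(key <= 2, "remembered", "forgotten"),
                  responses$trial_id)
}

#' Segment a continuous recording into epochs
#'
#' Cuts one epoch per trial over the half-open interval \code{[t0, t1)}
#' relative to cue onset (sample index = cue onset + round(t * rate)), keeps
#' only the non-EOG channels, and attaches labels from the response table.
#' Trials truncated by the recording edge are logged as rejected("edge").
#'
#' @param session a preprocessed [RawSession-class].
#' @param t0,t1 epoch bounds in seconds relative to cue (default -0.1, 2.9).
#' @return an [EpochSet-class].
#' @export
segmentEpochs <- function(session, t0 = -0.1, t1 = 2.9) {
  fs <- session@samplingRate
  m <- session@montage
  chn <- eegChannels(m)
  cues <- session@events[session@events$kind == "cue", ]
  epLen <- round(t1 * fs) - round(t0 * fs)
  labels <- if (nrow(session@responses))
    labelTrials(session@responses) else character(0)
  ns <- ncol(session@signal)
  ok <- logical(nrow(cues))
  starts <- integer(nrow(cues))
  for (i in seq_len(nrow(cues))) {
    s <- cues$onset_sample[i] + round(t0 * fs)
    ok[i] <- s >= 1L && s + epLen - 1L <= ns
    starts[i] <- s
  }
  dat <- array(0, c(sum(ok), length(chn), epLen),
               dimnames = list(NULL, chn, NULL))
  kept <- which(ok)
  for (j in seq_along(kept))
    dat[j, , ] <- session@signal[chn, starts[kept[j]] + 0:(epLen - 1L)]
  ids <- cues$trial_id[kept]
  mov <- rep(FALSE, length(ids))
  if (nrow(session@annotations)) {
    mi <- match(ids, session@annotations$trial_id)
    mov <- !is.na(mi) & session@annotations$movement[mi]
  }
  lab <- if (length(labels)) unname(labels[as.character(ids)])
         else rep(NA_character_, length(ids))
  rej <- data.frame(trial_id = cues$trial_id[!ok],
                    reason = rep("edge", sum(!ok)))
  new("EpochSet", data = dat, samplingRate = fs, tStart = t0,
      channelNames = chn, labels = lab, trialIds = as.integer(ids),
      movement = mov, rejected = rej,
      provenance = c(session@provenance, "segment"))
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the 100 ms pre-cue window
#' \code{[-0.1, 0)} so that window's post-correction mean is exactly zero.
#'
#' @param epochs an [EpochSet-class] starting at or before -0.1 s.
#' @return the corrected [EpochSet-class].
#' @export
baselineCorrect <- function(epochs) {
  if (epochs@tStart > -0.1 + 1e-9)
    stop("epochs must include the [-0.1, 0) s baseline window")
  idx <- windowIndices(-0.1, 0, epochs@tStart, epochs@samplingRate)
  base <- apply(epochs@data[, , idx, drop = FALSE], c(1L, 2L), mean)
  epochs@data <- epochs@data - as.vector(base)  # recycles over dim 3
  stampProvenance(epochs, "baseline")
}

#' Reject artifact trials
#'
#' Drops a trial iff any sample in any channel exceeds the amplitude
#' threshold in absolute value (strictly; a peak exactly at the threshold is
#' retained), or the trial carries a movement annotation. Retained trials are
#' not modified in any way.
#'
#' @param epochs a baseline-corrected [EpochSet-class].
#' @param threshold amplitude threshold in microvolts (default 50).
#' @return the [EpochSet-class] of retained trials; the rejection log gains
#'   one row per dropped trial with reason "amplitude" or "movement".
#' @export
rejectArtifacts <- function(epochs, threshold = 50) {
  n <- nTrials(epochs)
  peak <- apply(abs(epochs@data), 1L, max)
  badAmp <- peak > threshold
  badMov <- if (length(epochs@movement) == n) epochs@movement
            else rep(FALSE, n)
  drop <- badAmp | badMov
  reason <- ifelse(badMov, "movement", "amplitude")[drop]
  keep <- which(!drop)
  rej <- rbind(epochs@rejected,
               data.frame(trial_id = epochs@trialIds[drop], reason = reason))
  epochs@data <- epochs@data[keep, , , drop = FALSE]
  epochs@labels <- epochs@labels[keep]
  epochs@trialIds <- epochs@trialIds[keep]
  epochs@movement <- epochs@movement[keep]
  epochs@rejected <- rej
  stampProvenance(epochs, sprintf("reject[%g]", threshold))
}

# decimate one EpochSet to targetRate; anti-alias low-pass at 0.8 x new
# Nyquist unless naive = TRUE (plain picking of every factor-th sample)
decimateEpochs <- function(epochs, targetRate = 25, naive = FALSE) {
  fs <- epochs@samplingRate
  if (fs == targetRate) return(epochs)
  factor <- fs / targetRate
  if (abs(factor - round(factor)) > 1e-9)
    stop("sampling rate must be an integer multiple of the target rate")
  factor <- round(factor)
  d <- dim(epochs@data)
  pick <- seq.int(1L, d[3L], by = factor)
  out <- array(0, c(d[1L], d[2L], length(pick)),
               dimnames = c(dimnames(epochs@data)[1:2], list(NULL)))
  if (naive) {
    out <- epochs@data[, , pick, drop = FALSE]
  } else {
    cutoff <- 0.4 * targetRate   # 0.8 x the new Nyquist
    gain <- function(f) 1 / (1 + (f / cutoff)^16)
    for (i in seq_len(d[1L]))
      for (ch in seq_len(d[2L]))
        out[i, ch, ] <- zeroPhaseApply(epochs@data[i, ch, ], fs, gain,
                                       minPadSec = 1)[pick]
  }
  epochs@data <- out
  epochs@samplingRate <- targetRate
  stampProvenance(epochs, sprintf("decimate[%g->%g%s]", fs, targetRate,
                                  if (naive) ",naive" else ""))
}

windowBounds <- function(window) {
  switch(window,
         entire = c(-0.1, 2.9),
         pre = c(0.3, 1.5),
         during = c(1.5, 2.7),
         stop("window must be 'entire', 'pre' or 'during'"))
}

#' Prepare normalized model input
#'
#' Decimates epochs to the model rate (anti-aliased by default), crops to the
#' requested analysis window (entire = [-0.1, 2.9) giving T = 75; pre =
#' [0.3, 1.5) and during = [1.5, 2.7) giving T = 30), and z-normalizes each
#' channel. When \code{stats} is supplied (training-set statistics) it is
#' used unchanged — never recomputed — so held-out trials can be scaled
#' without leakage; otherwise statistics are computed from the given trials
#' and returned in the result.
#'
#' @param epochs an [EpochSet-class] on the non-EOG channels.
#' @param window "entire", "pre" or "during".
#' @param targetRate model sampling rate in Hz (25).
#' @param stats optional list(mean=, sd=) of per-channel statistics.
#' @param naiveDecimate skip the anti-aliasing low-pass and pick every
#'   factor-th sample.
#' @return a [ModelInputSet-class]; \code{inputStats()} returns the
#'   statistics actually used.
#' @export
prepareInput <- function(epochs, window = "entire", targetRate = 25,
                         stats = NULL, naiveDecimate = FALSE) {
  bounds <- windowBounds(window)
  dec <- decimateEpochs(epochs, targetRate, naive = naiveDecimate)
  i0 <- (bounds[1L] - dec@tStart) * targetRate
  i1 <- (bounds[2L] - dec@tStart) * targetRate
  if (abs(i0 - round(i0)) > 1e-9 || abs(i1 - round(i1)) > 1e-9)
    stop("window bounds are not sample-aligned at ", targetRate, " Hz")
  idx <- windowIndices(bounds[1L], bounds[2L], dec@tStart, targetRate)
  dat <- dec@data[, , idx, drop = FALSE]
  chn <- dec@channelNames
  if (is.null(stats)) {
    mu <- apply(dat, 2L, mean)
    sdv <- apply(dat, 2L, stats::sd)
    sdv[sdv == 0] <- 1
    stats <- list(mean = stats::setNames(mu, chn),
                  sd = stats::setNames(sdv, chn))
  } else {
    if (!all(chn %in% names(stats$mean)))
      stop("supplied stats do not cover all channels")
  }
  for (ch in seq_along(chn))
    dat[, ch, ] <- (dat[, ch, ] - stats$mean[[chn[ch]]]) /
      stats$sd[[chn[ch]]]
  new("ModelInputSet", data = dat, window = window, stats = stats,
      channelNames = chn, labels = dec@labels, trialIds = dec@trialIds,
      samplingRate = targetRate)
}

#' Run the full preprocessing chain
#'
#' Convenience wrapper applying the six steps in order: linked-mastoid
#' re-referencing, zero-phase band-pass, EOG regression, segmentation,
#' baseline correction and artifact rejection.
#'
#' @param session a [RawSession-class].
#' @param low,high band-pass edges in Hz.
#' @param t0,t1 epoch bounds in seconds.
#' @param threshold rejection threshold in microvolts.
#' @return an [EpochSet-class] of retained, labeled trials.
#' @export
preprocessSession <- function(session, low = 0.05, high = 15,
                              t0 = -0.1, t1 = 2.9, threshold = 50) {
  session <- reReference(session)
  session <- bandpassFilter(session, low, high)
  session <- regressEOG(session)
  epochs <- segmentEpochs(session, t0, t1)
  epochs <- baselineCorrect(epochs)
  rejectArtifacts(epochs, threshold)
}
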