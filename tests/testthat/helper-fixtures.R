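# Small fixtures built in code.

quietCfg <- function(...) {
  # all stochastic and artifact terms off unless overridden
  args <- utils::modifyList(
    list(noiseSigma = 0, whiteSigma = 0, blinkRate = 0, transientRate = 0,
         driftTrialFraction = 0, thetaAmp = 0, thetaAmpDiff = 0),
    list(...))
  do.call(simConfig, args)
}

# a minimal 6-channel montage for fast preprocessing tests
tinyMontage <- function() {
  montage(c("Fp1", "Cz", "TP9", "TP10", "VEOG", "HEOG"),
          eogChannels = c("VEOG", "HEOG"),
          mastoidChannels = c("TP9", "TP10"))
}

# hand-built RawSession around a given signal matrix
makeSession <- function(signal, mont, fs = 500, nTrials = 0) {
  ev <- if (nTrials > 0) {
    cue <- round(seq(0.5, by = 3.7, length.out = nTrials) * fs)
    data.frame(trial_id = rep(seq_len(nTrials), each = 2),
               onset_sample = as.vector(rbind(cue, cue + round(1.5 * fs))),
               kind = rep(c("cue", "word"), nTrials))
  } else data.frame(trial_id = integer(), onset_sample = integer(),
                    kind = character())
  resp <- if (nTrials > 0)
    data.frame(trial_id = seq_len(nTrials),
               key = rep(c(1, 4), length.out = nTrials))
    else data.frame(trial_id = integer(), key = integer())
  rownames(signal) <- mont@channelNames
  new("RawSession", signal = signal, samplingRate = fs, events = ev,
      responses = resp,
      annotations = if (nTrials > 0)
        data.frame(trial_id = seq_len(nTrials), movement = FALSE)
        else data.frame(trial_id = integer(), movement = logical()),
      montage = mont, truthLabels = character(), provenance = "fixture")
}

# EpochSet built directly from an array
makeEpochs <- function(dat, labels, fs = 500, tStart = -0.1,
                       channels = NULL, movement = NULL) {
  n <- dim(dat)[1]
  if (is.null(channels)) channels <- paste0("C", seq_len(dim(dat)[2]))
  if (is.null(movement)) movement <- rep(FALSE, n)
  new("EpochSet", data = dat, samplingRate = fs, tStart = tStart,
      channelNames = channels, labels = labels, trialIds = seq_len(n),
      movement = movement,
      rejected = data.frame(trial_id = integer(), reason = character()),
      provenance = "fixture")
}
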