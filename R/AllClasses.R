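#' @import methods
NULL

#' Electrode montage
#'
#' Describes the recording montage: ordered 10/10-system channel labels, which
#' channels are electrooculogram (EOG) channels, and which channels sit on the
#' mastoids and define the linked-mastoid reference.
#'
#' @slot channelNames ordered character vector of channel labels.
#' @slot eogChannels subset of \code{channelNames} carrying eye movement
#'   signals (VEOG, HEOG); excluded from model input.
#' @slot mastoidChannels subset of \code{channelNames} averaged to form the
#'   linked-mastoid reference.
#' @seealso [defaultMontage()]
#' @export
setClass("Montage",
  representation(
    channelNames    = "character",
    eogChannels     = "character",
    mastoidChannels = "character"
  )
)

setValidity("Montage", function(object) {
  msg <- character()
  if (anyDuplicated(object@channelNames))
    msg <- c(msg, "channelNames must be unique")
  if (!all(object@eogChannels %in% object@channelNames))
    msg <- c(msg, "eogChannels must be a subset of channelNames")
  if (!all(object@mastoidChannels %in% object@channelNames))
    msg <- c(msg, "mastoidChannels must be a subset of channelNames")
  if (length(intersect(object@eogChannels, object@mastoidChannels)) > 0L)
    msg <- c(msg, "eogChannels and mastoidChannels must be disjoint")
  if (length(msg)) msg else TRUE
})

#' Synthetic session configuration
#'
#' Parameters of the synthetic subsequent-memory-effect EEG generator. Times
#' are seconds relative to cue onset (cue at 0, word at 1.5 by default),
#' amplitudes are microvolts. The class-dependent terms are a sustained
#' negative-going shift over the pre-stimulus window and a sustained
#' positive-going shift over the during-stimulus window, both restricted to
#' \code{effectChannels}, plus a theta-amplitude difference.
#'
#' @slot nTrials number of study trials.
#' @slot pRemembered probability that a trial is later remembered.
#' @slot samplingRate sampling rate in Hz.
#' @slot cueTime,wordTime cue and word onset in seconds (word - cue = 1.5 s).
#' @slot trialSpan epoch span in seconds relative to cue, half-open.
#' @slot itiGap seconds between the end of one epoch span and the next cue
#'   (response pause plus the fixed 0.6 s inter-stimulus interval).
#' @slot effectChannels channels carrying the class-dependent shift.
#' @slot preWindow,duringWindow the two analysis windows in seconds.
#' @slot preEffect,duringEffect class-difference amplitudes in microvolts
#'   (remembered minus forgotten); the pre-stimulus default is negative.
#' @slot thetaFreq,thetaAmp,thetaAmpDiff theta oscillation frequency (Hz),
#'   base amplitude, and remembered-class amplitude increment.
#' @slot noiseSigma standard deviation of the 1/f^alpha background (uV).
#' @slot whiteSigma standard deviation of the additive white noise (uV).
#' @slot oneOverFExponent spectral exponent alpha of the background.
#' @slot blinkRate blink events per second, mirrored on VEOG.
#' @slot blinkAmp blink amplitude on VEOG in microvolts.
#' @slot transientRate rate (events/s) of sub-threshold spatially coherent
#'   transient artifacts (residual muscle/electrode activity that survives
#'   amplitude-based rejection).
#' @slot transientAmp peak amplitude cap of those transients in microvolts
#'   (kept below the rejection threshold).
#' @slot driftTrialFraction fraction of trials given a slow drift exceeding
#'   the +/-50 uV rejection threshold.
#' @slot driftAmp drift endpoint amplitude in microvolts.
#' @slot seed integer seed making the session reproducible.
#' @seealso [simConfig()], [simulateSession()]
#' @export
setClass("SimConfig",
  representation(
    nTrials            = "integer",
    pRemembered        = "numeric",
    samplingRate       = "numeric",
    cueTime            = "numeric",
    wordTime           = "numeric",
    trialSpan          = "numeric",
    itiGap             = "numeric",
    effectChannels     = "character",
    preWindow          = "numeric",
    duringWindow       = "numeric",
    preEffect          = "numeric",
    duringEffect       = "numeric",
    thetaFreq          = "numeric",
    thetaAmp           = "numeric",
    thetaAmpDiff       = "numeric",
    noiseSigma         = "numeric",
    whiteSigma         = "numeric",
    oneOverFExponent   = "numeric",
    blinkRate          = "numeric",
    blinkAmp           = "numeric",
    transientRate      = "numeric",
    transientAmp       = "numeric",
    driftTrialFraction = "numeric",
    driftAmp           = "numeric",
    seed               = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nTrials < 1L) msg <- c(msg, "nTrials must be >= 1")
  if (object@pRemembered < 0 || object@pRemembered > 1)
    msg <- c(msg, "pRemembered must be in [0, 1]")
  if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be positive")
  if (length(object@trialSpan) != 2L || diff(object@trialSpan) <= 0)
    msg <- c(msg, "trialSpan must be an increasing pair of times")
  if (object@driftTrialFraction < 0 || object@driftTrialFraction > 1)
    msg <- c(msg, "driftTrialFraction must be in [0, 1]")
  if (!isTRUE(all.equal(object@wordTime - object@cueTime, 1.5)))
    msg <- c(msg, "word onset must follow the cue by 1.5 s")
  if (length(msg)) msg else TRUE
})

#' Continuous EEG recording with event metadata
#'
#' A continuous multichannel recording plus the event, response and annotation
#' tables needed to segment and label trials. When produced by the simulator,
#' \code{truthLabels} carries the generating class of each trial.
#'
#' @slot signal channels x samples matrix of microvolts, rows named by channel.
#' @slot samplingRate sampling rate in Hz.
#' @slot events data.frame with columns \code{trial_id}, \code{onset_sample}
#'   (1-based), \code{kind} ("cue" or "word").
#' @slot responses data.frame with columns \code{trial_id}, \code{key} (1-5).
#' @slot annotations data.frame with columns \code{trial_id}, \code{movement}.
#' @slot montage the [Montage-class].
#' @slot truthLabels character per-trial class ("remembered"/"forgotten") or
#'   length zero for real recordings.
#' @slot provenance character log of applied processing steps.
#' @export
setClass("RawSession",
  representation(
    signal       = "matrix",
    samplingRate = "numeric",
    events       = "data.frame",
    responses    = "data.frame",
    annotations  = "data.frame",
    montage      = "Montage",
    truthLabels  = "character",
    provenance   = "character"
  )
)

setValidity("RawSession", function(object) {
  msg <- character()
  if (nrow(object@signal) != length(object@montage@channelNames))
    msg <- c(msg, "signal must have one row per montage channel")
  ev <- object@events
  if (nrow(ev)) {
    need <- c("trial_id", "onset_sample", "kind")
    if (!all(need %in% names(ev))) {
      msg <- c(msg, "events needs columns trial_id, onset_sample, kind")
    } else {
      if (is.unsorted(ev$onset_sample, strictly = TRUE))
        msg <- c(msg, "event onsets must be strictly increasing")
      cue  <- ev[ev$kind == "cue", ]
      word <- ev[ev$kind == "word", ]
      if (!setequal(cue$trial_id, word$trial_id) ||
          anyDuplicated(cue$trial_id) || anyDuplicated(word$trial_id)) {
        msg <- c(msg, "every trial needs exactly one cue and one word event")
      } else {
        gap <- word$onset_sample[match(cue$trial_id, word$trial_id)] -
          cue$onset_sample
        if (any(gap != round(1.5 * object@samplingRate)))
          msg <- c(msg, "word onset must follow the cue by 1.5 s")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Segmented, labeled EEG trials
#'
#' Trials x channels x samples array of epochs time-locked to cue onset, with
#' per-trial class labels and a log of rejected trials. After finalization
#' (artifact rejection) the EOG channels have been dropped.
#'
#' @slot data trials x channels x samples numeric array (microvolts).
#' @slot samplingRate sampling rate in Hz.
#' @slot tStart epoch start in seconds relative to cue (default -0.1).
#' @slot channelNames channel labels for the second dimension.
#' @slot labels per-trial class, "remembered" or "forgotten" (NA if unlabeled).
#' @slot trialIds integer trial identifiers.
#' @slot movement logical per-trial movement-annotation flag.
#' @slot rejected data.frame (\code{trial_id}, \code{reason}) of dropped trials.
#' @slot provenance character log of applied processing steps.
#' @export
setClass("EpochSet",
  representation(
    data         = "array",
    samplingRate = "numeric",
    tStart       = "numeric",
    channelNames = "character",
    labels       = "character",
    trialIds     = "integer",
    movement     = "logical",
    rejected     = "data.frame",
    provenance   = "character"
  ),
  prototype(movement = logical())
)

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L)
    msg <- c(msg, "data must be a trials x channels x samples array")
  else {
    if (d[2L] != length(object@channelNames))
      msg <- c(msg, "channelNames must match dim 2 of data")
    if (d[1L] != length(object@labels) || d[1L] != length(object@trialIds))
      msg <- c(msg, "labels and trialIds must match dim 1 of data")
  }
  off <- -object@tStart * object@samplingRate
  if (abs(off - round(off)) > 1e-9)
    msg <- c(msg, "tStart must be a whole number of samples")
  if (length(msg)) msg else TRUE
})

#' Normalized model input matrices
#'
#' Decimated, window-cropped and z-normalized input matrices, one N_ch x T
#' matrix per trial, together with the per-channel normalization statistics
#' actually used (so held-out trials can be scaled with training-set
#' statistics and leakage can be audited).
#'
#' @slot data trials x channels x T array.
#' @slot window "entire", "pre" or "during".
#' @slot stats list with named numeric vectors \code{mean} and \code{sd}.
#' @slot channelNames channel labels.
#' @slot labels,trialIds as in [EpochSet-class].
#' @slot samplingRate rate after decimation (25 Hz).
#' @export
setClass("ModelInputSet",
  representation(
    data         = "array",
    window       = "character",
    stats        = "list",
    channelNames = "character",
    labels       = "character",
    trialIds     = "integer",
    samplingRate = "numeric"
  )
)

setValidity("ModelInputSet", function(object) {
  msg <- character()
  if (!object@window %in% c("entire", "pre", "during"))
    msg <- c(msg, "window must be entire, pre or during")
  want <- if (object@window == "entire") 75L else 30L
  if (dim(object@data)[3L] != want)
    msg <- c(msg, sprintf("window '%s' must have T = %d samples",
                          object@window, want))
  if (length(msg)) msg else TRUE
})

#' Network hyperparameters
#'
#' Architecture and training hyperparameters of the five-layer network: input
#' N_ch x T, a spatial convolution layer with \code{nC} maps (kernels span all
#' channels at one time index, stride 1), a temporal convolution-plus-
#' subsampling layer whose map m has \code{p[m]} neurons (non-overlapping
#' receptive fields of size K_m = T / p[m]), a hidden layer of \code{q}
#' neurons and a two-neuron output layer.
#'
#' @slot nCh input channels (M of the spatial kernels).
#' @slot tLen input length T (75 for the entire window, 30 for pre/during).
#' @slot nC number of spatial maps.
#' @slot p integer vector of temporal map sizes P_m; each must divide tLen.
#' @slot q hidden layer size.
#' @slot a,b scaled-tanh activation constants (1.7159 and 2/3).
#' @slot learningRate SGD step size.
#' @slot maxEpochs,patience epoch budget and early-stopping patience.
#' @slot valFraction fraction of training samples held out for validation.
#' @slot nRestarts independent random initializations; the run with the
#'   lowest validation MSE (on the one shared split) is kept.
#' @slot init "uniform" (default) or "gaussian" weight initialization.
#' @slot seed integer seed (NA to use the caller's RNG state).
#' @seealso [networkConfig()], [countParams()]
#' @export
setClass("NetworkConfig",
  representation(
    nCh          = "integer",
    tLen         = "integer",
    nC           = "integer",
    p            = "integer",
    q            = "integer",
    a            = "numeric",
    b            = "numeric",
    learningRate = "numeric",
    maxEpochs    = "integer",
    patience     = "integer",
    valFraction  = "numeric",
    nRestarts    = "integer",
    init         = "character",
    seed         = "integer"
  )
)

setValidity("NetworkConfig", function(object) {
  msg <- character()
  if (object@nC < 1L) msg <- c(msg, "nC must be >= 1")
  if (length(object@p) != object@nC)
    msg <- c(msg, "p must list one map size per spatial map (length nC)")
  if (any(object@tLen %% object@p != 0L))
    msg <- c(msg, "every map size P_m must divide T (K_m = T / P_m integral)")
  if (!object@init %in% c("uniform", "gaussian"))
    msg <- c(msg, "init must be 'uniform' or 'gaussian'")
  if (object@valFraction <= 0 || object@valFraction >= 1)
    msg <- c(msg, "valFraction must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Learnable network parameters
#'
#' Kernels, weights and biases of the five-layer network, stored per layer.
#' Spatial kernel m has M = N_ch weights and one bias; temporal kernel m has
#' K_m weights and one bias; the two dense layers are full weight matrices.
#'
#' @slot spatialKernels nC x M matrix, one kernel per row.
#' @slot spatialBias numeric of length nC.
#' @slot temporalKernels list of numeric vectors, kernel m of length K_m.
#' @slot temporalBias numeric of length nC.
#' @slot hiddenW Q x sum(P) matrix; @slot hiddenB numeric Q.
#' @slot outW 2 x Q matrix; @slot outB numeric 2.
#' @export
setClass("NetworkParams",
  representation(
    spatialKernels  = "matrix",
    spatialBias     = "numeric",
    temporalKernels = "list",
    temporalBias    = "numeric",
    hiddenW         = "matrix",
    hiddenB         = "numeric",
    outW            = "matrix",
    outB            = "numeric"
  )
)

#' Training result
#'
#' Best-on-validation parameters with the per-epoch error history.
#'
#' @slot params best [NetworkParams-class] (validation-error minimizer).
#' @slot config the [NetworkConfig-class] used.
#' @slot history data.frame with columns epoch, trainMSE, valMSE.
#' @slot stoppedEpoch last epoch run; @slot bestEpoch validation minimizer.
#' @export
setClass("TrainResult",
  representation(
    params       = "NetworkParams",
    config       = "NetworkConfig",
    history      = "data.frame",
    stoppedEpoch = "integer",
    bestEpoch    = "integer"
  )
)

#' Leave-pair-out fold plan
#'
#' Each fold holds one trial of each class for testing (paired folds); when
#' classes are unequal, the leftover majority-class trials are tested in
#' singleton folds, so every trial is tested exactly once.
#'
#' @slot folds list of lists with integer elements \code{test}, \code{train}.
#' @slot k number of folds.
#' @export
setClass("FoldPlan",
  representation(folds = "list", k = "integer")
)

#' Cross-validation result
#'
#' Pooled per-trial predictions with accuracy and an exact one-sided binomial
#' test against chance (0.5).
#'
#' @slot predictions data.frame (trial_id, fold, truth, predicted).
#' @slot accuracy pooled proportion correct.
#' @slot nCorrect,nTotal counts.
#' @slot pValue one-sided exact binomial tail P(X >= nCorrect | nTotal, 0.5).
#' @slot significant logical, pValue < 0.05.
#' @slot model,window character tags of what was evaluated.
#' @export
setClass("CVResult",
  representation(
    predictions = "data.frame",
    accuracy    = "numeric",
    nCorrect    = "integer",
    nTotal      = "integer",
    pValue      = "numeric",
    significant = "logical",
    model       = "character",
    window      = "character"
  )
)

#' Channel weight map
#'
#' Per-channel discriminant scores derived from the spatial kernels of one or
#' more trained networks: mean absolute input-to-spatial-layer weight per
#' channel, min-max scaled to [0, 1].
#'
#' @slot scores named numeric in [0, 1], one per non-EOG channel.
#' @slot window the input window the models were trained on.
#' @slot nModels number of models averaged.
#' @export
setClass("ChannelWeightMap",
  representation(scores = "numeric", window = "character", nModels = "integer")
)

#' Grand-averaged ERP report
#'
#' Per-class grand-averaged ERPs (individual participant averages first, then
#' averaged with equal participant weight) and paired t-tests across
#' participants on window-mean amplitudes.
#'
#' @slot grandAverage list with channels x time matrices \code{remembered}
#'   and \code{forgotten}.
#' @slot time time axis in seconds relative to cue.
#' @slot channelNames channel labels.
#' @slot windowStats data.frame (window, meanRemembered, meanForgotten,
#'   difference, t, p) for the pre- and during-stimulus windows.
#' @slot nParticipants number of participants entering the grand average.
#' @export
setClass("SMEReport",
  representation(
    grandAverage  = "list",
    time          = "numeric",
    channelNames  = "character",
    windowStats   = "data.frame",
    nParticipants = "integer"
  )
)

#' Classifier specification
#'
#' Virtual parent of the classifier specifications driven by
#' [crossValidate()]. Every subclass implements [prepareContext()] (label-free
#' feature precomputation shared across folds), [fitClassifier()] (trained on
#' one fold's training trials only) and [predictClassifier()].
#'
#' @slot name short model name used in reports.
#' @export
setClass("ClassifierSpec", representation("VIRTUAL", name = "character"))

#' @rdname ClassifierSpec-class
#' @slot config template [NetworkConfig-class]; nCh and tLen are overwritten
#'   from the data at fit time.
#' @export
setClass("ConvEEGNNSpec", contains = "ClassifierSpec",
  representation(config = "NetworkConfig"))

#' @rdname ClassifierSpec-class
#' @slot lambda ridge added to the pooled covariance (relative to its mean
#'   diagonal) to stabilize high-dimensional fits.
#' @export
setClass("LDASpec", contains = "ClassifierSpec",
  representation(lambda = "numeric"))

#' @rdname ClassifierSpec-class
#' @slot hidden hidden layer sizes, \code{10} (ANN-1) or \code{c(20, 10)}
#'   (ANN-2); first hidden layer scaled tanh, later layers logistic.
#' @slot learningRate,maxEpochs,patience SGD settings (shared machinery with
#'   the convolutional network).
#' @export
setClass("ANNSpec", contains = "ClassifierSpec",
  representation(hidden = "integer", learningRate = "numeric",
                 maxEpochs = "integer", patience = "integer"))

#' @rdname ClassifierSpec-class
#' @slot degree polynomial kernel degree (cubic by default).
#' @slot costGrid soft-margin costs tried on an internal validation split.
#' @export
setClass("SVMSpec", contains = "ClassifierSpec",
  representation(degree = "integer", costGrid = "numeric"))

#' @rdname ClassifierSpec-class
#' @slot nPairs number of CSP filter pairs per window.
#' @slot rule fusion rule: "mean" of standardized decision values (default)
#'   or "vote".
#' @export
setClass("SVMLDAFusionSpec", contains = "ClassifierSpec",
  representation(nPairs = "integer", rule = "character"))

#' @rdname ClassifierSpec-class
#' @slot bands center frequencies (Hz) of the Morlet band-power features.
#' @slot cycles Morlet width in cycles.
#' @export
setClass("CWTSVMSpec", contains = "ClassifierSpec",
  representation(bands = "numeric", cycles = "numeric"))
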