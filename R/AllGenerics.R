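#' Accessors
#'
#' Small accessor generics shared by the data containers.
#'
#' @param object a package object.
#' @param ... unused.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nTrials", function(object) standardGeneric("nTrials"))

#' @rdname accessors
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))

#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))

#' @rdname accessors
#' @export
setGeneric("trialLabels", function(object) standardGeneric("trialLabels"))

#' @rdname accessors
#' @export
setGeneric("trialIds", function(object) standardGeneric("trialIds"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("epochData", function(object) standardGeneric("epochData"))

#' @rdname accessors
#' @export
setGeneric("rejectedTrials", function(object) standardGeneric("rejectedTrials"))

#' @rdname accessors
#' @export
setGeneric("inputStats", function(object) standardGeneric("inputStats"))

#' Label-free per-dataset feature preparation
#'
#' Computes everything a classifier needs that does not depend on trial
#' labels (decimation, window cropping, wavelet transforms), once per
#' dataset, so cross-validation folds can share it without leakage.
#'
#' @param spec a [ClassifierSpec-class].
#' @param epochs an [EpochSet-class] at the recording rate.
#' @param window "entire", "pre" or "during".
#' @return an opaque context list passed to [fitClassifier()].
#' @export
setGeneric("prepareContext",
  function(spec, epochs, window = "entire") standardGeneric("prepareContext"))

#' Fit a classifier on one fold's training trials
#'
#' All label-dependent computation (normalization statistics, CSP filters,
#' network training, internal validation splits) uses only the trials indexed
#' by \code{trainIdx}.
#'
#' @param spec a [ClassifierSpec-class].
#' @param context result of [prepareContext()].
#' @param trainIdx integer indices of the training trials.
#' @param seed integer seed for any stochastic step.
#' @return a fitted model object.
#' @export
setGeneric("fitClassifier",
  function(spec, context, trainIdx, seed = NULL)
    standardGeneric("fitClassifier"))

#' Predict trial labels with a fitted classifier
#'
#' @param spec a [ClassifierSpec-class].
#' @param model result of [fitClassifier()].
#' @param context result of [prepareContext()].
#' @param testIdx integer indices of the trials to predict.
#' @return character vector of "remembered"/"forgotten".
#' @export
setGeneric("predictClassifier",
  function(spec, model, context, testIdx) standardGeneric("predictClassifier"))
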