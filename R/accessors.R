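#' @rdname accessors
setMethod("nChannels", "Montage", function(object) length(object@channelNames))

#' @rdname accessors
setMethod("channelNames", "Montage", function(object) object@channelNames)

#' @rdname accessors
setMethod("nChannels", "RawSession", function(object) nrow(object@signal))

#' @rdname accessors
setMethod("channelNames", "RawSession",
  function(object) object@montage@channelNames)

#' @rdname accessors
setMethod("samplingRate", "RawSession", function(object) object@samplingRate)

#' @rdname accessors
setMethod("nTrials", "RawSession",
  function(object) length(unique(object@events$trial_id)))

#' @rdname accessors
setMethod("nTrials", "EpochSet", function(object) dim(object@data)[1L])

#' @rdname accessors
setMethod("nChannels", "EpochSet", function(object) dim(object@data)[2L])

#' @rdname accessors
setMethod("channelNames", "EpochSet", function(object) object@channelNames)

#' @rdname accessors
setMethod("trialLabels", "EpochSet", function(object) object@labels)

#' @rdname accessors
setMethod("trialIds", "EpochSet", function(object) object@trialIds)

#' @rdname accessors
setMethod("samplingRate", "EpochSet", function(object) object@samplingRate)

#' @rdname accessors
setMethod("epochData", "EpochSet", function(object) object@data)

#' @rdname accessors
setMethod("rejectedTrials", "EpochSet", function(object) object@rejected)

#' @rdname accessors
setMethod("nTrials", "ModelInputSet", function(object) dim(object@data)[1L])

#' @rdname accessors
setMethod("nChannels", "ModelInputSet", function(object) dim(object@data)[2L])

#' @rdname accessors
setMethod("channelNames", "ModelInputSet", function(object) object@channelNames)

#' @rdname accessors
setMethod("trialLabels", "ModelInputSet", function(object) object@labels)

#' @rdname accessors
setMethod("trialIds", "ModelInputSet", function(object) object@trialIds)

#' @rdname accessors
setMethod("epochData", "ModelInputSet", function(object) object@data)

#' @rdname accessors
setMethod("inputStats", "ModelInputSet", function(object) object@stats)

setMethod("show", "Montage", function(object) {
  cat("Montage with", nChannels(object), "channels\n")
  cat("  EOG:", paste(object@eogChannels, collapse = ", "), "\n")
  cat("  mastoids:", paste(object@mastoidChannels, collapse = ", "), "\n")
})

setMethod("show", "RawSession", function(object) {
  cat(sprintf("RawSession: %d channels x %d samples at %g Hz (%.1f s)\n",
              nrow(object@signal), ncol(object@signal), object@samplingRate,
              ncol(object@signal) / object@samplingRate))
  cat(sprintf("  %d trials, %d responses, %d truth labels\n",
              nTrials(object), nrow(object@responses),
              length(object@truthLabels)))
  if (length(object@provenance))
    cat("  provenance:", paste(object@provenance, collapse = " -> "), "\n")
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet: %d trials x %d channels x %d samples at %g Hz\n",
              d[1L], d[2L], d[3L], object@samplingRate))
  tab <- table(factor(object@labels, c("remembered", "forgotten")))
  cat(sprintf("  labels: %d remembered / %d forgotten; %d rejected\n",
              tab[["remembered"]], tab[["forgotten"]], nrow(object@rejected)))
  if (length(object@provenance))
    cat("  provenance:", paste(object@provenance, collapse = " -> "), "\n")
})

setMethod("show", "ModelInputSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("ModelInputSet (%s window): %d trials x %d channels x T=%d\n",
              object@window, d[1L], d[2L], d[3L]))
})

setMethod("show", "NetworkConfig", function(object) {
  cat(sprintf("NetworkConfig: input %d x %d, N_c=%d, P=(%s), Q=%d\n",
              object@nCh, object@tLen, object@nC,
              paste(object@p, collapse = ","), object@q))
  cat(sprintf("  lr=%g, maxEpochs=%d, patience=%d, init=%s\n",
              object@learningRate, object@maxEpochs, object@patience,
              object@init))
})

setMethod("show", "TrainResult", function(object) {
  cat(sprintf("TrainResult: stopped at epoch %d, best epoch %d (val MSE %.5f)\n",
              object@stoppedEpoch, object@bestEpoch,
              object@history$valMSE[object@bestEpoch]))
})

setMethod("show", "FoldPlan", function(object) {
  sizes <- vapply(object@folds, function(f) length(f$test), integer(1))
  cat(sprintf("FoldPlan: %d folds (%d paired, %d singleton)\n",
              object@k, sum(sizes == 2L), sum(sizes == 1L)))
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult [%s, %s window]: accuracy %.2f%% (%d/%d), p = %.4g%s\n",
              object@model, object@window, 100 * object@accuracy,
              object@nCorrect, object@nTotal, object@pValue,
              if (object@significant) " *" else ""))
})

setMethod("show", "ChannelWeightMap", function(object) {
  top <- names(sort(object@scores, decreasing = TRUE))[1:3]
  cat(sprintf("ChannelWeightMap (%s window, %d models); top-3: %s\n",
              object@window, object@nModels, paste(top, collapse = " ")))
})

setMethod("show", "SMEReport", function(object) {
  cat(sprintf("SMEReport over %d participants\n", object@nParticipants))
  print(object@windowStats, row.names = FALSE)
})
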