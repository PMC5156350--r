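# Single-file containers: a one-line JSON header (shapes, labels, config)
# followed by little-endian float64 payload. Used to pass epochs and trained
# models between pipeline stages and the command-line tools.

writeHeaderPayload <- function(path, header, payload) {
  con <- file(path, "wb")
  on.exit(close(con))
  hj <- jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA)
  writeLines(as.character(hj), con)
  writeBin(as.numeric(payload), con, size = 8L, endian = "little")
  invisible(path)
}

readHeaderPayload <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- jsonlite::fromJSON(readLines(con, n = 1L))
  payload <- readBin(con, numeric(), n = file.size(path) %/% 8L, size = 8L,
                     endian = "little")
  list(header = header, payload = payload)
}

#' Write / read an epoch container
#'
#' Stores an [EpochSet-class] as one file: a JSON header (dimensions, channel
#' names, labels, trial ids, movement flags, rejection log, provenance)
#' followed by the raw sample payload.
#'
#' @param epochs an [EpochSet-class].
#' @param path output file.
#' @return \code{writeEpochs}: the path, invisibly; \code{readEpochs}: the
#'   restored [EpochSet-class].
#' @export
writeEpochs <- function(epochs, path) {
  header <- list(
    container = "epochs", dims = dim(epochs@data),
    samplingRate = epochs@samplingRate, tStart = epochs@tStart,
    channelNames = epochs@channelNames, labels = epochs@labels,
    trialIds = epochs@trialIds, movement = epochs@movement,
    rejected = epochs@rejected, provenance = epochs@provenance)
  writeHeaderPayload(path, header, epochs@data)
}

#' @rdname writeEpochs
#' @export
readEpochs <- function(path) {
  hp <- readHeaderPayload(path)
  h <- hp$header
  if (!identical(h$container, "epochs")) stop("not an epoch container")
  rej <- as.data.frame(h$rejected)
  if (!nrow(rej)) rej <- data.frame(trial_id = integer(),
                                    reason = character())
  new("EpochSet",
      data = array(hp$payload, h$dims,
                   dimnames = list(NULL, h$channelNames, NULL)),
      samplingRate = h$samplingRate, tStart = h$tStart,
      channelNames = h$channelNames,
      labels = as.character(h$labels), trialIds = as.integer(h$trialIds),
      movement = as.logical(h$movement), rejected = rej,
      provenance = as.character(h$provenance))
}

#' Write / read a trained model container
#'
#' Stores a [TrainResult-class] as one file: a JSON header with the
#' [NetworkConfig-class] and training history, followed by the flat
#' parameter vector.
#'
#' @param fit a [TrainResult-class].
#' @param path output file.
#' @return \code{writeModel}: the path, invisibly; \code{readModel}: the
#'   restored [TrainResult-class].
#' @export
writeModel <- function(fit, path) {
  cfg <- fit@config
  header <- list(
    container = "conveegnn-model",
    config = list(nCh = cfg@nCh, tLen = cfg@tLen, nC = cfg@nC, p = cfg@p,
                  q = cfg@q, a = cfg@a, b = cfg@b,
                  learningRate = cfg@learningRate,
                  maxEpochs = cfg@maxEpochs, patience = cfg@patience,
                  valFraction = cfg@valFraction, nRestarts = cfg@nRestarts,
                  init = cfg@init, seed = cfg@seed),
    history = fit@history, stoppedEpoch = fit@stoppedEpoch,
    bestEpoch = fit@bestEpoch)
  writeHeaderPayload(path, header, flattenParams(fit@params))
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  hp <- readHeaderPayload(path)
  h <- hp$header
  if (!identical(h$container, "conveegnn-model")) stop("not a model container")
  cf <- h$config
  cfg <- networkConfig(cf$nCh, cf$tLen, cf$nC, cf$p, cf$q, cf$a, cf$b,
                       cf$learningRate, cf$maxEpochs, cf$patience,
                       cf$valFraction, cf$nRestarts, cf$init,
                       if (is.null(cf$seed)) NA else cf$seed)
  new("TrainResult", params = unflattenParams(hp$payload, cfg),
      config = cfg, history = as.data.frame(h$history),
      stoppedEpoch = as.integer(h$stoppedEpoch),
      bestEpoch = as.integer(h$bestEpoch))
}
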