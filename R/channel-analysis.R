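#' Channel weight map from trained networks
#'
#' The absolute value of an input-to-spatial-layer weight measures a
#' channel's discriminant capability. Scores are computed as the mean over
#' maps and models of the absolute spatial-kernel weights per channel
#' (absolute value first, so signed kernels cannot cancel), then min-max
#' scaled to [0, 1]. The map is invariant to kernel sign flips and to model
#' ordering.
#'
#' @param models a single fit or a list: [TrainResult-class] or
#'   [NetworkParams-class] objects.
#' @param window window tag carried into the result.
#' @param chNames channel names for the kernel columns (taken from the
#'   montage by default).
#' @return a [ChannelWeightMap-class].
#' @export
weightMap <- function(models, window = "entire",
                      chNames = eegChannels(defaultMontage())) {
  if (!is.list(models)) models <- list(models)
  if (!length(models)) stop("need at least one trained model")
  kern <- function(m) {
    if (is(m, "TrainResult")) m <- m@params
    if (!is(m, "NetworkParams")) stop("models must be fits or parameters")
    m@spatialKernels
  }
  perModel <- vapply(models, function(m) colMeans(abs(kern(m))),
                     numeric(ncol(kern(models[[1L]]))))
  score <- rowMeans(as.matrix(perModel))
  rng <- range(score)
  scaled <- if (rng[2L] > rng[1L]) (score - rng[1L]) / diff(rng)
            else rep(0, length(score))
  if (length(chNames) != length(scaled))
    stop("chNames must match the kernel width")
  new("ChannelWeightMap", scores = stats::setNames(scaled, chNames),
      window = window, nModels = length(models))
}

#' Highest-scoring channels of a weight map
#'
#' @param map a [ChannelWeightMap-class].
#' @param k number of channels (default 3).
#' @return character vector of channel names, descending score; ties broken
#'   by montage order.
#' @export
topChannels <- function(map, k = 3L) {
  if (k > length(map@scores)) stop("k exceeds the number of channels")
  ord <- order(-map@scores, seq_along(map@scores))
  names(map@scores)[ord[seq_len(k)]]
}

#' Grand-averaged ERP and subsequent-memory-effect report
#'
#' Averages each participant's trials into per-class individual ERPs, then
#' averages those into the grand-averaged ERP with equal participant weight
#' (so duplicating a participant's trials does not change the result).
#' Window-mean amplitudes over the pre-stimulus [0.3, 1.5) s and
#' during-stimulus [1.5, 2.7) s windows on the report channels are compared
#' between classes with a paired two-sided t-test across participants.
#'
#' @param epochSets list of labeled [EpochSet-class] objects, one per
#'   participant.
#' @param channels channels entering the window-mean amplitudes (default the
#'   representative frontal site Fp1).
#' @return an [SMEReport-class].
#' @export
grandAverageSME <- function(epochSets, channels = "Fp1") {
  if (!is.list(epochSets)) epochSets <- list(epochSets)
  indiv <- list()
  for (i in seq_along(epochSets)) {
    ep <- epochSets[[i]]
    lab <- trialLabels(ep)
    if (!all(c("remembered", "forgotten") %in% lab)) {
      warning("participant ", i, " lacks a class; excluded")
      next
    }
    avg <- function(cl)
      apply(ep@data[lab == cl, , , drop = FALSE], c(2L, 3L), mean)
    indiv[[length(indiv) + 1L]] <-
      list(remembered = avg("remembered"), forgotten = avg("forgotten"),
           tStart = ep@tStart, fs = ep@samplingRate,
           channelNames = channelNames(ep))
  }
  if (!length(indiv)) stop("no participant with both classes")
  nP <- length(indiv)
  fs <- indiv[[1L]]$fs
  tStart <- indiv[[1L]]$tStart
  chn <- indiv[[1L]]$channelNames
  ga <- list(
    remembered = Reduce(`+`, lapply(indiv, `[[`, "remembered")) / nP,
    forgotten = Reduce(`+`, lapply(indiv, `[[`, "forgotten")) / nP)
  nT <- ncol(ga$remembered)
  time <- tStart + (seq_len(nT) - 1L) / fs
  chIdx <- match(channels, chn)
  if (anyNA(chIdx)) stop("report channels absent from the epochs")
  wins <- list(pre = c(0.3, 1.5), during = c(1.5, 2.7))
  rows <- lapply(names(wins), function(wn) {
    idx <- windowIndices(wins[[wn]][1L], wins[[wn]][2L], tStart, fs)
    m <- vapply(indiv, function(p) c(
      mean(p$remembered[chIdx, idx, drop = FALSE]),
      mean(p$forgotten[chIdx, idx, drop = FALSE])), numeric(2))
    diffs <- m[1L, ] - m[2L, ]
    tt <- if (nP >= 2L && stats::sd(diffs) > 1e-12)
      stats::t.test(m[1L, ], m[2L, ], paired = TRUE)
      else NULL
    data.frame(window = wn,
               meanRemembered = mean(m[1L, ]),
               meanForgotten = mean(m[2L, ]),
               difference = mean(diffs),
               t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               p = if (is.null(tt)) NA_real_ else tt$p.value)
  })
  new("SMEReport", grandAverage = ga, time = time, channelNames = chn,
      windowStats = do.call(rbind, rows), nParticipants = as.integer(nP))
}
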