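# Minimal EDF (16-bit) and BrainVision (IEEE float32) writers/readers for
# continuous sessions. Event, response, annotation, truth-label and montage
# tables travel as CSV sidecars next to the signal file in both formats and
# are authoritative for the round trip.

padField <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

sidecarPaths <- function(base) {
  list(events = paste0(base, "_events.csv"),
       responses = paste0(base, "_responses.csv"),
       annotations = paste0(base, "_annotations.csv"),
       labels = paste0(base, "_labels.csv"),
       montage = paste0(base, "_montage.csv"))
}

writeSidecars <- function(session, base) {
  p <- sidecarPaths(base)
  utils::write.csv(session@events, p$events, row.names = FALSE)
  utils::write.csv(session@responses, p$responses, row.names = FALSE)
  utils::write.csv(session@annotations, p$annotations, row.names = FALSE)
  if (length(session@truthLabels))
    utils::write.csv(data.frame(trial_id = seq_along(session@truthLabels),
                                label = session@truthLabels),
                     p$labels, row.names = FALSE)
  m <- session@montage
  utils::write.csv(data.frame(channel = m@channelNames,
                              is_eog = m@channelNames %in% m@eogChannels,
                              is_mastoid = m@channelNames %in%
                                m@mastoidChannels),
                   p$montage, row.names = FALSE)
  unlist(p[c(1:3, 5)], use.names = FALSE)
}

readSidecars <- function(base) {
  p <- sidecarPaths(base)
  for (need in c("events", "responses", "montage"))
    if (!file.exists(p[[need]]))
      stop("missing sidecar: ", p[[need]])
  mt <- utils::read.csv(p$montage, stringsAsFactors = FALSE)
  mont <- montage(mt$channel, eogChannels = mt$channel[mt$is_eog],
                  mastoidChannels = mt$channel[mt$is_mastoid])
  labels <- character(0)
  if (file.exists(p$labels))
    labels <- utils::read.csv(p$labels, stringsAsFactors = FALSE)$label
  ann <- if (file.exists(p$annotations))
    utils::read.csv(p$annotations, stringsAsFactors = FALSE)
    else data.frame(trial_id = integer(), movement = logical())
  list(events = utils::read.csv(p$events, stringsAsFactors = FALSE),
       responses = utils::read.csv(p$responses, stringsAsFactors = FALSE),
       annotations = ann, montage = mont, labels = labels)
}

writeEDF <- function(session, base) {
  path <- paste0(base, ".edf")
  sig <- session@signal
  fs <- session@samplingRate
  nch <- nrow(sig)
  ns <- ncol(sig)
  spr <- round(fs)                        # one-second data records
  nRec <- ceiling(ns / spr)
  physMax <- pmax(apply(abs(sig), 1L, max), 1)
  digMax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wf <- function(x, width) writeChar(padField(x, width), con, width,
                                     eos = NULL)
  wf("0", 8)
  wf("X X X X", 80)
  wf("Startdate 01-JAN-2026 X X X", 80)
  wf("01.01.26", 8)
  wf("00.00.00", 8)
  wf(256 * (nch + 1L), 8)
  wf(sprintf("NS=%d", ns), 44)            # true sample count (reader hint)
  wf(nRec, 8)
  wf("1", 8)
  wf(nch, 4)
  for (ch in rownames(sig)) wf(ch, 16)
  for (i in seq_len(nch)) wf("AgAgCl electrode", 80)
  for (i in seq_len(nch)) wf("uV", 8)
  for (i in seq_len(nch)) wf(sprintf("%.6g", -physMax[i]), 8)
  for (i in seq_len(nch)) wf(sprintf("%.6g", physMax[i]), 8)
  for (i in seq_len(nch)) wf(-digMax, 8)
  for (i in seq_len(nch)) wf(digMax, 8)
  for (i in seq_len(nch)) wf("", 80)
  for (i in seq_len(nch)) wf(spr, 8)
  for (i in seq_len(nch)) wf("", 32)
  scale <- physMax / digMax
  padded <- cbind(sig, matrix(0, nch, nRec * spr - ns))
  for (r in seq_len(nRec)) {
    cols <- (r - 1L) * spr + seq_len(spr)
    block <- round(padded[, cols, drop = FALSE] / scale)
    writeBin(as.integer(t(block)), con, size = 2L, endian = "little")
  }
  path
}

readEDF <- function(base) {
  path <- paste0(base, ".edf")
  con <- file(path, "rb")
  on.exit(close(con))
  rf <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rf(8); rf(80); rf(80); rf(8); rf(8)
  rf(8)                                   # header bytes
  reserved <- rf(44)
  nRec <- as.integer(rf(8))
  rf(8)                                   # record duration
  nch <- as.integer(rf(4))
  labels <- vapply(seq_len(nch), function(i) rf(16), character(1))
  for (i in seq_len(nch)) rf(80)
  for (i in seq_len(nch)) rf(8)
  physMin <- as.numeric(vapply(seq_len(nch), function(i) rf(8), character(1)))
  physMax <- as.numeric(vapply(seq_len(nch), function(i) rf(8), character(1)))
  digMin <- as.numeric(vapply(seq_len(nch), function(i) rf(8), character(1)))
  digMax <- as.numeric(vapply(seq_len(nch), function(i) rf(8), character(1)))
  for (i in seq_len(nch)) rf(80)
  spr <- as.integer(vapply(seq_len(nch), function(i) rf(8), character(1)))
  for (i in seq_len(nch)) rf(32)
  fs <- spr[1L]
  sig <- matrix(0, nch, nRec * spr[1L], dimnames = list(labels, NULL))
  scale <- (physMax - physMin) / (digMax - digMin)
  for (r in seq_len(nRec)) {
    raw <- readBin(con, integer(), n = sum(spr), size = 2L,
                   endian = "little")    # channel-blocked within the record
    for (ch in seq_len(nch))
      sig[ch, (r - 1L) * spr[1L] + seq_len(spr[ch])] <-
        raw[(ch - 1L) * spr[ch] + seq_len(spr[ch])] * scale[ch] +
        physMin[ch] - digMin[ch] * scale[ch]
  }
  nsTrue <- if (grepl("^NS=", reserved))
    as.integer(sub("^NS=", "", reserved)) else ncol(sig)
  list(signal = sig[, seq_len(nsTrue), drop = FALSE], samplingRate = fs)
}

writeBrainVision <- function(session, base) {
  name <- basename(base)
  vhdr <- paste0(base, ".vhdr")
  vmrk <- paste0(base, ".vmrk")
  eeg <- paste0(base, ".eeg")
  sig <- session@signal
  nch <- nrow(sig)
  lines <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", name, ".eeg"),
    paste0("MarkerFile=", name, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nch),
    paste0("SamplingInterval=", format(1e6 / session@samplingRate)),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,uV", seq_len(nch), rownames(sig)))
  writeLines(lines, vhdr)
  ev <- session@events
  mk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
          "[Common Infos]", paste0("DataFile=", name, ".eeg"),
          "[Marker Infos]",
          "Mk1=New Segment,,1,1,0,00000000000000000000",
          sprintf("Mk%d=Stimulus,S%3d,%d,1,0", seq_len(nrow(ev)) + 1L,
                  ifelse(ev$kind == "cue", 1L, 2L), ev$onset_sample))
  writeLines(mk, vmrk)
  con <- file(eeg, "wb")
  writeBin(as.numeric(as.vector(sig)), con, size = 4L, endian = "little")
  close(con)
  c(vhdr, vmrk, eeg)
}

readBrainVision <- function(base) {
  vhdr <- paste0(base, ".vhdr")
  lines <- readLines(vhdr, warn = FALSE)
  getVal <- function(key) {
    ln <- grep(paste0("^", key, "="), lines, value = TRUE)[1L]
    sub(paste0("^", key, "="), "", ln)
  }
  nch <- as.integer(getVal("NumberOfChannels"))
  fs <- 1e6 / as.numeric(getVal("SamplingInterval"))
  chLines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  labels <- vapply(strsplit(sub("^Ch[0-9]+=", "", chLines), ","),
                   `[[`, character(1), 1L)
  eeg <- file.path(dirname(vhdr), getVal("DataFile"))
  raw <- readBin(eeg, numeric(), n = file.size(eeg) %/% 4L, size = 4L,
                 endian = "little")
  sig <- matrix(raw, nrow = nch, dimnames = list(labels, NULL))
  list(signal = sig, samplingRate = fs)
}

#' Write a session to disk
#'
#' Writes the continuous signal as EDF (16-bit, one-second data records,
#' symmetric per-channel scaling) or a BrainVision triplet
#' (.vhdr/.vmrk/.eeg, IEEE float32 multiplexed), plus CSV sidecars for the
#' event, response, annotation, truth-label and montage tables. EDF
#' quantization bounds the absolute signal error by half a digitization step
#' per channel; BrainVision stores float32.
#'
#' @param session a [RawSession-class].
#' @param base output path without extension.
#' @param format "edf" or "brainvision".
#' @return invisibly, the written file paths.
#' @export
writeSession <- function(session, base, format = c("edf", "brainvision")) {
  format <- match.arg(format)
  dir.create(dirname(base), recursive = TRUE, showWarnings = FALSE)
  main <- switch(format,
                 edf = writeEDF(session, base),
                 brainvision = writeBrainVision(session, base))
  invisible(c(main, writeSidecars(session, base)))
}

#' Read a session from disk
#'
#' Counterpart of [writeSession()]: restores the signal from the EDF or
#' BrainVision file and the tables from the CSV sidecars, validating that
#' every trial has a paired cue and word event.
#'
#' @param base path without extension, as given to [writeSession()].
#' @param format "edf" or "brainvision"; inferred from the files present
#'   when omitted.
#' @return a [RawSession-class].
#' @export
readSession <- function(base, format = NULL) {
  if (is.null(format)) {
    format <- if (file.exists(paste0(base, ".edf"))) "edf"
              else if (file.exists(paste0(base, ".vhdr"))) "brainvision"
              else stop("no EDF or BrainVision file at ", base)
  }
  raw <- switch(format, edf = readEDF(base),
                brainvision = readBrainVision(base),
                stop("unsupported format: ", format))
  side <- readSidecars(base)
  if (!setequal(rownames(raw$signal), side$montage@channelNames))
    stop("signal channels do not match the montage sidecar")
  raw$signal <- raw$signal[side$montage@channelNames, , drop = FALSE]
  ev <- side$events
  for (id in unique(ev$trial_id)) {
    kinds <- ev$kind[ev$trial_id == id]
    if (sum(kinds == "cue") != 1L || sum(kinds == "word") != 1L)
      stop("trial ", id, " must have exactly one cue and one word event")
  }
  new("RawSession", signal = raw$signal, samplingRate = raw$samplingRate,
      events = ev, responses = side$responses,
      annotations = side$annotations, montage = side$montage,
      truthLabels = side$labels, provenance = paste0("read[", format, "]"))
}
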