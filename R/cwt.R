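# Morlet continuous wavelet band power. The wavelet is a complex exponential
# under a Gaussian envelope whose width is set in cycles (sigma_t =
# cycles / (2 pi f)); power is the squared magnitude of the convolution.

#' Morlet wavelet power time series
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param freq center frequency in Hz.
#' @param cycles wavelet width in cycles (default 6).
#' @return numeric vector of instantaneous band power, same length as x.
#' @export
morletPower <- function(x, fs, freq, cycles = 6) {
  n <- length(x)
  sigmaT <- cycles / (2 * pi * freq)
  half <- ceiling(4 * sigmaT * fs)
  t <- (-half:half) / fs
  w <- exp(2i * pi * freq * t) * exp(-t^2 / (2 * sigmaT^2))
  w <- w / sum(abs(w))
  nf <- stats::nextn(n + length(w), c(2L, 3L, 5L))
  X <- stats::fft(c(x, rep(0, nf - n)))
  W <- stats::fft(c(w, rep(0, nf - length(w))))
  conv <- stats::fft(X * W, inverse = TRUE) / nf
  Mod(conv[half + seq_len(n)])^2
}

# channel pools by anterior-posterior row: frontal / central / posterior
channelGroups <- function(names) {
  row <- channelRow(names)
  list(frontal = which(row <= 2L),
       central = which(row >= 3L & row <= 5L),
       posterior = which(row >= 6L))
}

# band x window x channel-group mean log power features per trial:
# bands (Hz) x {pre, during} x {frontal, central, posterior}
cwtFeatureMatrix <- function(epochs, bands = c(4.00, 6.42, 11.26),
                             cycles = 6) {
  d <- dim(epochs@data)
  fs <- epochs@samplingRate
  groups <- channelGroups(epochs@channelNames)
  wins <- list(pre = windowIndices(0.3, 1.5, epochs@tStart, fs),
               during = windowIndices(1.5, 2.7, epochs@tStart, fs))
  feat <- matrix(0, d[1L], length(bands) * length(wins) * length(groups))
  nm <- character(0)
  col <- 0L
  for (b in bands) for (wn in names(wins)) for (gn in names(groups)) {
    col <- col + 1L
    nm[col] <- sprintf("f%.2f_%s_%s", b, wn, gn)
  }
  for (i in seq_len(d[1L])) {
    pw <- array(0, c(d[2L], length(bands), d[3L]))
    for (ch in seq_len(d[2L]))
      for (bi in seq_along(bands))
        pw[ch, bi, ] <- morletPower(epochs@data[i, ch, ], fs, bands[bi],
                                    cycles)
    col <- 0L
    for (bi in seq_along(bands)) for (wn in names(wins))
      for (g in groups) {
        col <- col + 1L
        feat[i, col] <- log(mean(pw[g, bi, wins[[wn]]]) + 1e-12)
      }
  }
  colnames(feat) <- nm
  feat
}
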