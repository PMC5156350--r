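#' Construct a montage
#'
#' @param channelNames ordered channel labels.
#' @param eogChannels EOG channel labels (subset of \code{channelNames}).
#' @param mastoidChannels mastoid channel labels used for re-referencing.
#' @return a [Montage-class].
#' @export
#' @examples
#' montage(c("Fz", "Cz", "M1", "M2", "VEOG"),
#'   eogChannels = "VEOG", mastoidChannels = c("M1", "M2"))
montage <- function(channelNames, eogChannels = character(),
                    mastoidChannels = character()) {
  new("Montage", channelNames = as.character(channelNames),
      eogChannels = as.character(eogChannels),
      mastoidChannels = as.character(mastoidChannels))
}

#' Default 32-channel recording montage
#'
#' The 32-channel cap layout used throughout: 30 scalp channels of the 10/10
#' system (including the mastoid sites TP9/TP10 that define the linked-mastoid
#' reference) plus the two EOG channels. Excluding the EOG channels leaves the
#' 30 channels used as model input.
#'
#' @return a [Montage-class] with 32 channels.
#' @export
#' @examples
#' m <- defaultMontage()
#' nChannels(m)                          # 32
#' setdiff(channelNames(m), m@eogChannels) # the 30 model channels
defaultMontage <- function() {
  scalp <- c(
    "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6",
    "T7", "C3", "Cz", "C4", "T8",
    "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
    "P7", "P3", "Pz", "P4", "P8",
    "O1", "Oz", "O2"
  )
  montage(c(scalp, "VEOG", "HEOG"),
          eogChannels = c("VEOG", "HEOG"),
          mastoidChannels = c("TP9", "TP10"))
}

#' Non-EOG channels of a montage
#'
#' @param m a [Montage-class].
#' @return character vector of the channels used as model input.
#' @export
eegChannels <- function(m) setdiff(m@channelNames, m@eogChannels)
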