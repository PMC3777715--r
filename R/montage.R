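#' Standard 29-channel 10-20 EEG montage
#'
#' The electrode labels used throughout the package, in fixed order, plus
#' the two electro-oculogram channels appended by the recording convention.
#' All connectivity matrices are indexed by [eeg_montage()] order.
#'
#' @return Character vector of 29 EEG channel labels.
#' @export
eeg_montage <- function() {
  c("Fp1", "Fp2", "AFz", "Fz", "F4", "F8", "F3", "F7",
    "FCz", "FC4", "FT8", "FC3", "FT7",
    "Cz", "C4", "T8", "C3", "T7",
    "CPz", "CP4", "CP3",
    "Pz", "P4", "P8", "P3", "P7",
    "Oz", "O2", "O1")
}

#' @rdname eeg_montage
#' @export
eog_labels <- function() c("VEOG", "HEOG")

#' Canonical frequency band table
#'
#' Five classical EEG bands with their edges in Hz.
#'
#' @return Named list of length-2 numeric vectors `c(low, high)`.
#' @export
eeg_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 12),
       beta = c(12, 30), gamma = c(30, 50))
}

# half-up rounding; base round() is banker's and the edge-count /
# embedding-dimension conventions here need 0.5 -> 1
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
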