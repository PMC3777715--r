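#' Construct a raw multichannel recording
#'
#' @param subject_id Subject identifier.
#' @param fs Sampling rate in Hz.
#' @param samples Channels x time numeric matrix in microvolts.
#' @param channel_labels Channel labels, one per row of `samples`.
#' @return An object of class `sl_recording`.
#' @export
recording <- function(subject_id, fs, samples, channel_labels) {
  samples <- as.matrix(samples)
  if (length(channel_labels) != nrow(samples))
    stop("channel_labels length (", length(channel_labels),
         ") does not match the number of sample rows (", nrow(samples), ")")
  if (fs <= 0) stop("fs must be positive")
  rownames(samples) <- channel_labels
  structure(list(subject_id = subject_id, fs = fs,
                 channel_labels = channel_labels, samples = samples),
            class = "sl_recording")
}

#' Preprocessing configuration
#'
#' Defaults reproduce the standard resting-EEG chain: 2 s epochs, +/-150 uV
#' rejection, decimation to 250 Hz, the first 10 clean epochs kept, and the
#' five classical frequency bands.
#'
#' @param epoch_seconds Epoch length in seconds.
#' @param reject_uV Absolute-amplitude rejection threshold in microvolts.
#' @param target_fs Rate after decimation, in Hz; must divide the native rate.
#' @param n_keep Number of artifact-free epochs retained per subject.
#' @param bands Named list of band edges as in [eeg_bands()].
#' @param filter_order Butterworth order for the zero-phase band filters.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(epoch_seconds = 2, reject_uV = 150,
                              target_fs = 250, n_keep = 10L,
                              bands = eeg_bands(), filter_order = 4L) {
  for (b in bands) if (b[1] >= b[2]) stop("band edges must be increasing")
  structure(list(epoch_seconds = epoch_seconds, reject_uV = reject_uV,
                 target_fs = target_fs, n_keep = as.integer(n_keep),
                 bands = bands, filter_order = as.integer(filter_order)),
            class = "preprocess_config")
}

new_epoch_set <- function(data, fs, channel_labels, rejected_mask,
                          band = NULL) {
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 rejected_mask = rejected_mask, band = band),
            class = "epoch_set")
}

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth filtering, the standard choice
#' when later synchronization analysis must not suffer phase distortion.
#'
#' @param x Numeric vector.
#' @param low,high Band edges in Hz.
#' @param fs Sampling rate in Hz.
#' @param order Filter order (effective order doubles under filtfilt).
#' @return Filtered vector of the same length.
#' @export
zero_phase_bandpass <- function(x, low, high, fs, order = 4L) {
  if (high >= fs / 2)
    stop("upper band edge ", high, " Hz violates Nyquist at fs = ", fs, " Hz")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}

# exact spectral-mask band-pass used by the synthetic generator, where
# arbitrary (possibly very low) normalized edges must stay stable
fft_bandpass <- function(x, low, high, fs) {
  n <- length(x)
  f <- abs(seq(0, fs, length.out = n + 1)[seq_len(n)])
  f <- pmin(f, fs - f)  # two-sided frequency axis
  keep <- f >= low & f <= high
  Re(stats::fft(stats::fft(x) * keep, inverse = TRUE)) / n
}

#' Remove ocular activity by EOG regression
#'
#' Regresses every EEG channel on the vertical and horizontal EOG channels
#' (ordinary least squares over the whole recording) and subtracts the
#' fitted ocular contribution. The EOG channels themselves pass through
#' unchanged. A zero-variance EOG channel contributes nothing.
#'
#' @param rec An `sl_recording` containing channels named `VEOG` and `HEOG`.
#' @return The corrected recording.
#' @export
correct_eog <- function(rec) {
  stopifnot(inherits(rec, "sl_recording"))
  missing <- setdiff(eog_labels(), rec$channel_labels)
  if (length(missing))
    stop("missing EOG channel(s): ", paste(missing, collapse = ", "))
  eog <- t(rec$samples[eog_labels(), , drop = FALSE])
  eeg_rows <- setdiff(rec$channel_labels, eog_labels())
  X <- cbind(intercept = 1, eog)
  coefs <- qr.coef(qr(X), t(rec$samples[eeg_rows, , drop = FALSE]))
  coefs[is.na(coefs)] <- 0
  fitted_eog <- eog %*% coefs[-1, , drop = FALSE]
  rec$samples[eeg_rows, ] <- rec$samples[eeg_rows, , drop = FALSE] -
    t(fitted_eog)
  rec
}

#' Segment a recording into epochs and flag amplitude artifacts
#'
#' Cuts consecutive non-overlapping epochs, flags every epoch in which any
#' EEG sample exceeds the rejection threshold (tested before baseline
#' correction), and baseline-corrects each epoch by subtracting its
#' per-channel mean. Only EEG channels enter the epoch set; EOG channels
#' have served their purpose by this stage.
#'
#' @param rec An `sl_recording` (ideally after [correct_eog()]).
#' @param cfg A [preprocess_config()].
#' @return An `epoch_set` with a logical `rejected_mask`.
#' @export
epoch_and_reject <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "sl_recording"))
  epoch_len <- round(cfg$epoch_seconds * rec$fs)
  n_epochs <- floor(ncol(rec$samples) / epoch_len)
  if (n_epochs < 1)
    stop("recording shorter than one epoch (", epoch_len, " samples)")
  eeg_rows <- intersect(rec$channel_labels, eeg_montage())
  if (!length(eeg_rows)) eeg_rows <- setdiff(rec$channel_labels, eog_labels())
  x <- rec$samples[eeg_rows, , drop = FALSE]
  n_ch <- length(eeg_rows)
  data <- array(NA_real_, dim = c(n_epochs, n_ch, epoch_len))
  rejected <- logical(n_epochs)
  for (e in seq_len(n_epochs)) {
    seg <- x[, (e - 1L) * epoch_len + seq_len(epoch_len), drop = FALSE]
    rejected[e] <- any(abs(seg) > cfg$reject_uV)
    data[e, , ] <- seg - rowMeans(seg)
  }
  if (all(rejected)) stop("all epochs rejected at +/-", cfg$reject_uV, " uV")
  new_epoch_set(data, rec$fs, eeg_rows, rejected)
}

#' Keep the first clean epochs in temporal order
#'
#' @param ep An `epoch_set`.
#' @param n_keep How many artifact-free epochs to retain.
#' @return An `epoch_set` containing exactly `n_keep` clean epochs.
#' @export
select_epochs <- function(ep, n_keep = 10L) {
  stopifnot(inherits(ep, "epoch_set"))
  clean <- which(!ep$rejected_mask)
  if (length(clean) < n_keep)
    stop("only ", length(clean), " artifact-free epochs available, need ",
         n_keep)
  keep <- clean[seq_len(n_keep)]
  new_epoch_set(ep$data[keep, , , drop = FALSE], ep$fs, ep$channel_labels,
                rep(FALSE, n_keep), ep$band)
}

#' Decimate epochs to a lower sampling rate
#'
#' Anti-alias low-pass filters each epoch (zero-phase Butterworth, cutoff
#' 0.4 x target rate) and keeps every q-th sample, where q is the integer
#' decimation factor.
#'
#' @param ep An `epoch_set`.
#' @param cfg A [preprocess_config()] supplying `target_fs`.
#' @return The decimated `epoch_set`.
#' @export
downsample_epochs <- function(ep, cfg = preprocess_config()) {
  stopifnot(inherits(ep, "epoch_set"))
  q <- ep$fs / cfg$target_fs
  if (q != round(q))
    stop("native rate ", ep$fs, " Hz is not an integer multiple of target ",
         cfg$target_fs, " Hz")
  q <- as.integer(q)
  if (q == 1L) return(ep)
  d <- dim(ep$data)
  out_len <- floor(d[3] / q)
  bf <- signal::butter(cfg$filter_order, (0.4 * cfg$target_fs) / (ep$fs / 2),
                       type = "low")
  out <- array(NA_real_, dim = c(d[1], d[2], out_len))
  pick <- seq(1L, by = q, length.out = out_len)
  for (e in seq_len(d[1]))
    for (ch in seq_len(d[2]))
      out[e, ch, ] <- signal::filtfilt(bf, ep$data[e, ch, ])[pick]
  new_epoch_set(out, cfg$target_fs, ep$channel_labels, ep$rejected_mask,
                ep$band)
}

#' Band-pass filter an epoch set
#'
#' @param ep An `epoch_set`.
#' @param band Band label present in `cfg$bands`.
#' @param cfg A [preprocess_config()].
#' @return The filtered `epoch_set` with its `band` label set.
#' @export
bandpass_epochs <- function(ep, band, cfg = preprocess_config()) {
  stopifnot(inherits(ep, "epoch_set"))
  if (!band %in% names(cfg$bands))
    stop("unknown band '", band, "'; expected one of ",
         paste(names(cfg$bands), collapse = ", "))
  edges <- cfg$bands[[band]]
  if (edges[2] >= ep$fs / 2)
    stop("band '", band, "' upper edge ", edges[2],
         " Hz violates Nyquist at fs = ", ep$fs, " Hz")
  d <- dim(ep$data)
  out <- ep$data
  bf <- signal::butter(cfg$filter_order, edges / (ep$fs / 2), type = "pass")
  for (e in seq_len(d[1]))
    for (ch in seq_len(d[2]))
      out[e, ch, ] <- signal::filtfilt(bf, ep$data[e, ch, ])
  new_epoch_set(out, ep$fs, ep$channel_labels, ep$rejected_mask, band)
}

#' Run the full preprocessing chain for one subject
#'
#' EOG regression, epoching with amplitude rejection, selection of the
#' first `n_keep` clean epochs, decimation, and band filtering, in that
#' order.
#'
#' @param rec An `sl_recording` with EOG channels.
#' @param cfg A [preprocess_config()].
#' @param bands Which bands to return (default: all in `cfg$bands`).
#' @return Named list of band-filtered `epoch_set` objects.
#' @export
preprocess_recording <- function(rec, cfg = preprocess_config(),
                                 bands = names(cfg$bands)) {
  ep <- epoch_and_reject(correct_eog(rec), cfg)
  ep <- select_epochs(ep, cfg$n_keep)
  ep <- downsample_epochs(ep, cfg)
  out <- lapply(bands, function(b) bandpass_epochs(ep, b, cfg))
  names(out) <- bands
  out
}
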