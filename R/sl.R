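#' Frequency-prior embedding parameters for synchronization likelihood
#'
#' Derives time-delay embedding parameters from the band of interest. The
#' lag spans roughly a third of the period of the fastest component,
#' `lag = round(fs / (3 * band_high))`; the embedding dimension covers the
#' slowest, `m = round(3 * band_high / band_low) + 1`; the Theiler window
#' excludes trivially autocorrelated neighbours, `w1 = 2 * lag * (m - 1)`;
#' and the outer window is sized so that roughly `n_ref` recurrences are
#' expected at recurrence probability `p_ref`,
#' `w2 = w1 + round(n_ref / p_ref)`. Rounding is half-up.
#'
#' @param band_low,band_high Band edges in Hz.
#' @param fs Sampling rate in Hz.
#' @param p_ref Recurrence probability fixing each channel's critical
#'   distance (default 0.01).
#' @param n_ref Nominal number of recurrences inside the outer window
#'   (default 10).
#' @return An object of class `embedding_params` with integer fields
#'   `lag`, `m`, `w1`, `w2` and numeric `p_ref`.
#' @export
embed_parameters <- function(band_low, band_high, fs, p_ref = 0.01,
                             n_ref = 10) {
  if (!(band_low > 0 && band_low < band_high && band_high <= fs / 2))
    stop("need 0 < band_low < band_high <= fs/2")
  if (!(p_ref > 0 && p_ref < 1)) stop("p_ref must lie in (0, 1)")
  lag <- max(1L, as.integer(round_half_up(fs / (3 * band_high))))
  m <- max(2L, as.integer(round_half_up(3 * band_high / band_low) + 1))
  w1 <- 2L * lag * (m - 1L)
  w2 <- w1 + as.integer(round_half_up(n_ref / p_ref))
  structure(list(lag = lag, m = m, w1 = w1, w2 = w2, p_ref = p_ref,
                 n_ref = n_ref), class = "embedding_params")
}

check_embedding_feasible <- function(params, n_epochs, epoch_len) {
  span <- (params$m - 1L) * params$lag
  if (epoch_len <= span)
    stop("epoch of ", epoch_len, " samples too short for embedding span ",
         span, " + 1; need at least ", span + 1L, " samples per epoch")
  n_vec <- epoch_len - span
  # a candidate exists iff some pair of embedding-vector start indices is
  # separated by more than w1 and less than w2 on the concatenated axis
  max_sep <- (n_epochs - 1L) * epoch_len + n_vec - 1L
  if (max_sep <= params$w1)
    stop("Theiler window w1 = ", params$w1, " excludes all candidate pairs; ",
         "need concatenated length > ", params$w1 + span + 1L,
         " samples (have ", n_epochs * epoch_len, ")")
  invisible(TRUE)
}

as_epoch_array <- function(x) {
  if (inherits(x, "epoch_set")) return(x$data)
  if (is.array(x) && length(dim(x)) == 3) return(x)
  stop("expected an epoch_set or a 3-d array (epochs x channels x samples)")
}

#' Synchronization likelihood between two signals
#'
#' SL measures generalized synchronization: the likelihood that state-space
#' recurrences of one signal coincide in time with recurrences of the
#' other. Both signals are delay-embedded; for each reference time the
#' critical distance of each channel is set so that a fraction `p_ref` of
#' candidate vectors (those inside the Theiler/outer window) count as
#' recurrences, and SL is the ratio of joint to single-channel recurrences
#' averaged over reference times. Identical (or affinely rescaled) signals
#' give SL = 1; independent signals give SL close to `p_ref`.
#'
#' @param x,y Numeric vectors of equal length, or matrices
#'   (epochs x samples) whose rows are analysed as separate epochs.
#' @param params An [embed_parameters()] object.
#' @param metric `"euclidean"` (default) or `"chebyshev"` state-space
#'   distance.
#' @return A single SL value in `(0, 1]`.
#' @export
sl_pair <- function(x, y, params, metric = c("euclidean", "chebyshev")) {
  metric <- match.arg(metric)
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (is.vector(y)) y <- matrix(y, nrow = 1)
  if (!all(dim(x) == dim(y))) stop("x and y must have identical shapes")
  if (stats::sd(as.vector(x)) < 1e-12 || stats::sd(as.vector(y)) < 1e-12)
    stop("constant signal: state-space distances are degenerate")
  check_embedding_feasible(params, nrow(x), ncol(x))
  data <- array(NA_real_, dim = c(nrow(x), 2L, ncol(x)))
  data[, 1L, ] <- x
  data[, 2L, ] <- y
  m <- .sl_kernel(data, params$lag, params$m, params$w1, params$w2,
                  params$p_ref, as.integer(metric == "chebyshev"))
  m[1L, 2L]
}

#' Pairwise synchronization-likelihood matrix
#'
#' Applies the SL measure to every unordered channel pair of a
#' band-filtered epoch set (406 pairs for the 29-channel montage).
#' Embedding vectors never span epoch boundaries; candidate recurrences may
#' come from any epoch subject to the Theiler and outer windows evaluated
#' on the concatenated sample index.
#'
#' @param epochs An `epoch_set` (or 3-d array epochs x channels x samples).
#' @param params An [embed_parameters()] object; typically band-matched via
#'   [embed_parameters()] on the epoch set's band.
#' @param metric State-space distance, as in [sl_pair()].
#' @param subject_id,band Optional annotations carried in attributes.
#' @return A symmetric numeric matrix with unit diagonal and class
#'   `sl_matrix`; attributes `subject_id`, `band`, `params`.
#' @export
sl_matrix <- function(epochs, params, metric = c("euclidean", "chebyshev"),
                      subject_id = NULL, band = NULL) {
  metric <- match.arg(metric)
  data <- as_epoch_array(epochs)
  labels <- if (inherits(epochs, "epoch_set")) epochs$channel_labels
            else dimnames(data)[[2]] %||% paste0("ch", seq_len(dim(data)[2]))
  band <- band %||% (if (inherits(epochs, "epoch_set")) epochs$band else NULL)
  sds <- apply(data, 2L, stats::sd)
  if (any(sds < 1e-12))
    stop("constant signal in channel(s): ",
         paste(labels[sds < 1e-12], collapse = ", "))
  check_embedding_feasible(params, dim(data)[1], dim(data)[3])
  m <- .sl_kernel(data, params$lag, params$m, params$w1, params$w2,
                  params$p_ref, as.integer(metric == "chebyshev"))
  dimnames(m) <- list(labels, labels)
  structure(m, class = c("sl_matrix", class(m)),
            subject_id = subject_id, band = band, params = params)
}

#' Mean synchronization likelihood of a connectivity matrix
#'
#' Arithmetic mean of the off-diagonal upper-triangle entries (the 406
#' informative values of a 29-channel matrix); the unit diagonal is always
#' excluded.
#'
#' @param m A symmetric SL matrix.
#' @return A single number.
#' @export
mean_sl <- function(m) {
  m <- unclass(m)
  mean(m[upper.tri(m)])
}
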