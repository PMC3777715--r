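#' Write a recording to disk
#'
#' Two interchange formats: `"delimited"` writes a tab-separated table,
#' one column per channel with a header row of channel labels and one row
#' per sample, plus a JSON sidecar `<path>.json` holding `subject_id` and
#' `fs`; `"edf"` writes a standard European Data Format (EDF) file with
#' 16-bit samples, one-second data records and per-channel physical
#' scaling in microvolts.
#'
#' @param rec An `sl_recording`.
#' @param path Output file path.
#' @param format `"delimited"` or `"edf"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("delimited", "edf")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "sl_recording"))
  if (format == "delimited") {
    m <- t(rec$samples)
    colnames(m) <- rec$channel_labels
    utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(subject_id = rec$subject_id, fs = rec$fs),
                         paste0(path, ".json"), auto_unbox = TRUE)
  } else {
    write_edf(rec, path)
  }
  invisible(path)
}

#' Read a recording from disk
#'
#' @param path File path (see [write_recording()] for the formats).
#' @param format `"delimited"` or `"edf"`.
#' @param fs Sampling rate in Hz, required for delimited input without a
#'   JSON sidecar.
#' @param subject_id Optional override for the subject identifier.
#' @return An `sl_recording` in microvolts.
#' @export
read_recording <- function(path, format = c("delimited", "edf"), fs = NULL,
                           subject_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "edf") return(read_edf(path, subject_id = subject_id))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    fs <- fs %||% meta$fs
    subject_id <- subject_id %||% meta$subject_id
  }
  if (is.null(fs)) stop("fs not given and no JSON sidecar found for ", path)
  m <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  recording(subject_id %||% basename(path), fs, t(as.matrix(m)),
            colnames(m))
}

pad_ascii <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

write_edf <- function(rec, path) {
  ns <- nrow(rec$samples)
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  n_rec <- floor(ncol(rec$samples) / fs)
  if (n_rec < 1) stop("recording shorter than one 1-s EDF data record")
  x <- rec$samples[, seq_len(n_rec * fs), drop = FALSE]
  pmin_ <- pmax_ <- numeric(ns)
  dig <- matrix(0L, ns, ncol(x))
  for (i in seq_len(ns)) {
    r <- max(abs(x[i, ]), 1e-6)
    pmin_[i] <- -r; pmax_[i] <- r
    dig[i, ] <- as.integer(round((x[i, ] - pmin_[i]) /
                                   (pmax_[i] - pmin_[i]) * 65535 - 32768))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * ns
  writeChar(paste0(
    pad_ascii("0", 8), pad_ascii(rec$subject_id %||% "X", 80),
    pad_ascii("Startdate 01-JAN-2000", 80),
    pad_ascii("01.01.00", 8), pad_ascii("00.00.00", 8),
    pad_ascii(hdr_bytes, 8), pad_ascii("", 44),
    pad_ascii(n_rec, 8), pad_ascii("1", 8), pad_ascii(ns, 4)),
    con, eos = NULL)
  fld <- function(vals, width)
    writeChar(paste(vapply(vals, pad_ascii, "", width), collapse = ""),
              con, eos = NULL)
  fld(rec$channel_labels, 16)
  fld(rep("AgAgCl electrode", ns), 80)
  fld(rep("uV", ns), 8)
  fld(formatC(pmin_, digits = 5, format = "g"), 8)
  fld(formatC(pmax_, digits = 5, format = "g"), 8)
  fld(rep(-32768L, ns), 8)
  fld(rep(32767L, ns), 8)
  fld(rep("", ns), 80)
  fld(rep(as.integer(fs), ns), 8)
  fld(rep("", ns), 32)
  for (r in seq_len(n_rec))
    for (i in seq_len(ns))
      writeBin(dig[i, (r - 1L) * fs + seq_len(fs)], con, size = 2L,
               endian = "little")
  invisible(path)
}

read_edf <- function(path, subject_id = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)                                   # version
  pid <- rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- suppressWarnings(as.integer(rd(8)))
  if (is.na(hdr_bytes)) stop("malformed EDF header: byte-count field")
  rd(44)
  n_rec <- suppressWarnings(as.integer(rd(8)))
  rec_dur <- suppressWarnings(as.numeric(rd(8)))
  ns <- suppressWarnings(as.integer(rd(4)))
  if (is.na(ns) || ns < 1) stop("malformed EDF header: signal-count field")
  if (is.na(rec_dur) || rec_dur <= 0)
    stop("malformed EDF header: record-duration field")
  sig_fld <- function(width, numeric = FALSE) {
    v <- vapply(seq_len(ns), function(i) rd(width), "")
    if (numeric) suppressWarnings(as.numeric(v)) else v
  }
  labels <- sig_fld(16); sig_fld(80)
  dims <- sig_fld(8)
  pmin_ <- sig_fld(8, TRUE); pmax_ <- sig_fld(8, TRUE)
  dmin <- sig_fld(8, TRUE); dmax <- sig_fld(8, TRUE)
  sig_fld(80)
  spr <- sig_fld(8, TRUE)
  sig_fld(32)
  if (any(is.na(c(pmin_, pmax_, dmin, dmax, spr))))
    stop("malformed EDF header: signal scaling fields")
  if (length(unique(spr)) != 1)
    stop("EDF signals with heterogeneous sampling rates are not supported")
  if (!all(dims %in% c("uV", "mV", "")))
    stop("unsupported physical dimension(s): ",
         paste(unique(setdiff(dims, c("uV", "mV", ""))), collapse = ", "))
  fs <- spr[1] / rec_dur
  if (is.na(n_rec) || n_rec < 0) {
    bytes <- file.size(path) - hdr_bytes
    n_rec <- bytes %/% (2 * sum(spr))
  }
  out <- matrix(NA_real_, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, integer(), n = spr[i], size = 2L, endian = "little")
      v <- (d - dmin[i]) * (pmax_[i] - pmin_[i]) / (dmax[i] - dmin[i]) + pmin_[i]
      if (dims[i] == "mV") v <- v * 1000
      out[i, (r - 1L) * spr[1] + seq_len(spr[1])] <- v
    }
  }
  recording(subject_id %||% pid, fs, out, labels)
}

#' Write / read a synchronization-likelihood matrix
#'
#' Tab-delimited square matrix with channel labels as header and row
#' names, plus a JSON manifest `<path>.json` carrying `subject_id`,
#' `band` and the embedding parameters.
#'
#' @param m An [sl_matrix()].
#' @param path File path.
#' @return `path` (write) or the matrix with its attributes restored
#'   (read).
#' @export
write_sl_matrix <- function(m, path) {
  utils::write.table(as.matrix(unclass(m)), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  p <- attr(m, "params")
  jsonlite::write_json(list(subject_id = attr(m, "subject_id"),
                            band = attr(m, "band"),
                            params = p[c("lag", "m", "w1", "w2", "p_ref",
                                         "n_ref")]),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_sl_matrix
#' @export
read_sl_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  out <- structure(m, class = c("sl_matrix", class(m)))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    attr(out, "subject_id") <- meta$subject_id
    attr(out, "band") <- meta$band
    if (!is.null(meta$params))
      attr(out, "params") <- structure(meta$params, class = "embedding_params")
  }
  out
}

#' Write / read the cohort metadata table
#'
#' Plain CSV with columns subject_id, group, age, sex, iq, education,
#' ymrs, madrs.
#'
#' @param meta Metadata data frame.
#' @param path File path.
#' @export
write_metadata <- function(meta, path) {
  utils::write.csv(meta, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
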