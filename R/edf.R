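## Minimal European Data Format (EDF) I/O: 16-bit samples, 1 s data records,
## one signal per EEG channel plus optional accelerometer signals. Covers the
## subset of EDF needed to exchange this package's recordings.

edf_pad <- function(s, n) {
  s <- substr(as.character(s), 1, n)
  formatC(s, width = n, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Signals are stored as 16-bit integers in 1 s data records with per-signal
#' physical scaling spanning the observed data range. The recording is
#' truncated to a whole number of records.
#'
#' @param rec an `eeg_recording`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires integer fs")
  fs <- as.integer(round(fs))
  sig <- rec$data
  labels <- edf_channel_labels(rec)
  if (!is.null(rec$accel)) sig <- cbind(sig, rec$accel)
  ns <- ncol(sig)
  n_rec <- nrow(sig) %/% fs
  if (n_rec < 1) stop("recording shorter than one 1 s data record")
  sig <- sig[seq_len(n_rec * fs), , drop = FALSE]

  pmin <- apply(sig, 2, min); pmax <- apply(sig, 2, max)
  flat <- pmax - pmin < 1e-9
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (ns + 1), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4),
    paste(vapply(labels, edf_pad, "", n = 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(vapply(rep("uV", ns), edf_pad, "", n = 8), collapse = ""),
    paste(vapply(sprintf("%.6g", pmin), edf_pad, "", n = 8), collapse = ""),
    paste(vapply(sprintf("%.6g", pmax), edf_pad, "", n = 8), collapse = ""),
    paste(vapply(rep(dmin, ns), edf_pad, "", n = 8), collapse = ""),
    paste(vapply(rep(dmax, ns), edf_pad, "", n = 8), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(vapply(rep(fs, ns), edf_pad, "", n = 8), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = ""))
  writeChar(hdr, con, eos = NULL)

  gain <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1) * fs + 1):(r * fs)
    for (j in seq_len(ns)) {
      dig <- round((sig[rows, j] - pmin[j]) * gain[j] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

edf_channel_labels <- function(rec) {
  labs <- sprintf("EEG %s", rec$labels)
  if (!is.null(rec$accel))
    labs <- c(labs, sprintf("Accel%d", seq_len(ncol(rec$accel))))
  labs
}

#' Read an EDF file written by [write_edf()] (or any 16-bit EDF with uniform
#' record duration)
#'
#' Signals labelled `Accel*` are returned in the `accel` slot.
#'
#' @param path EDF file
#' @return an `eeg_recording`
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8 + 80 + 80 + 8 + 8 + 8 + 44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(w) trimws(vapply(seq_len(ns), function(i) rd(w), ""))
  labels <- fld(16); fld(80); fld(8)
  pmin <- as.numeric(fld(8)); pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8))
  fld(32)
  if (length(unique(spr)) != 1) stop("non-uniform sampling rates not supported")
  fs <- spr[1] / rec_dur
  out <- matrix(0, nrow = n_rec * spr[1], ncol = ns)
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1) * spr[1] + 1):(r * spr[1])
    for (j in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[1], size = 2, endian = "little",
                     signed = TRUE)
      out[rows, j] <- (dig - dmin[j]) / (dmax[j] - dmin[j]) *
        (pmax[j] - pmin[j]) + pmin[j]
    }
  }
  is_acc <- grepl("^Accel", labels)
  eeg <- out[, !is_acc, drop = FALSE]
  labs <- sub("^EEG ", "", labels[!is_acc])
  eeg_recording(eeg, fs, channel_ids = seq_len(ncol(eeg)) - 1L, labels = labs,
                accel = if (any(is_acc)) out[, is_acc, drop = FALSE] else NULL)
}
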