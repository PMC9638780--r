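#' The coherence frequency grid: 99 bins from 1 to 50 Hz in 0.5 Hz steps
#' @export
COH_GRID <- seq(1, 50, by = 0.5)

#' Decimate a recording by an integer factor with Chebyshev anti-aliasing
#'
#' Order-8 Chebyshev type-I low-pass (0.05 dB ripple, cutoff 0.8 x new
#' Nyquist) applied forward-backward (zero phase), then subsampled.
#'
#' @param rec an `eeg_recording`
#' @param factor integer decimation factor (default 8)
#' @return the decimated `eeg_recording` (accelerometer decimated alongside)
#' @export
decimate_recording <- function(rec, factor = 8) {
  stopifnot(inherits(rec, "eeg_recording"))
  factor <- as.integer(factor)
  if (abs(rec$fs / factor - round(rec$fs / factor)) > 1e-9)
    stop("fs not divisible by decimation factor")
  flt <- signal::cheby1(8, 0.05, 0.8 / factor)
  dec <- function(x) signal::filtfilt(flt, x)[seq(1, length(x), by = factor)]
  dat <- apply(rec$data, 2, dec)
  acc <- if (!is.null(rec$accel)) apply(rec$accel, 2, dec) else NULL
  eeg_recording(dat, rec$fs / factor, rec$channel_ids, rec$labels, accel = acc)
}

#' @rdname decimate_recording
#' @export
decimate8 <- function(rec) decimate_recording(rec, 8L)

## Welch-averaged one- and cross-spectra of a set of signals.
## cols: samples x channels; returns list(freq, S[channel, channel, bin])
welch_cross_spectra <- function(cols, fs, nperseg = NULL, grid = COH_GRID) {
  nperseg <- nperseg %||% as.integer(round(2 * fs))   # 0.5 Hz native bins
  n <- nrow(cols)
  if (n < nperseg) stop("signal shorter than one Welch segment")
  hop <- nperseg %/% 2
  starts <- seq(1, n - nperseg + 1, by = hop)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))  # Hann
  fr <- (0:(nperseg - 1)) * fs / nperseg
  bins <- match(round(grid * 2) / 2, round(fr * 2) / 2)
  if (any(is.na(bins))) stop("requested grid not representable at this fs")
  nc <- ncol(cols)
  S <- array(0 + 0i, dim = c(nc, nc, length(bins)))
  for (s in starts) {
    seg <- cols[s:(s + nperseg - 1), , drop = FALSE]
    seg <- sweep(seg, 2, colMeans(seg))
    X <- stats::mvfft(seg * win)[bins, , drop = FALSE]
    for (b in seq_along(bins)) {
      v <- X[b, ]
      S[, , b] <- S[, , b] + outer(v, Conj(v))
    }
  }
  S <- S / length(starts)
  list(freq = grid, S = S)
}

#' Imaginary part of the complex coherency between two signals
#'
#' Welch-averaged cross- and auto-spectra (2 s Hann segments, 50% overlap, so
#' the native resolution is exactly 0.5 Hz) give the complex coherency
#' `Sxy / sqrt(Sxx Syy)`; its imaginary part is returned on the 99-bin
#' 1-50 Hz grid. Zero-lag (volume-conducted) mixing contributes nothing to
#' the imaginary part; a genuine time lag does.
#'
#' @param x,y equal-length traces
#' @param fs sampling rate in Hz
#' @param grid frequency bin centres (default 1-50 Hz by 0.5)
#' @return numeric vector of per-bin values in `[-1, 1]` with attribute
#'   `freq`; bins where either auto-spectrum vanishes are `NA`
#' @export
imaginary_coherency <- function(x, y, fs, grid = COH_GRID) {
  if (length(x) != length(y)) stop("length mismatch")
  cs <- welch_cross_spectra(cbind(x, y), fs, grid = grid)
  sxx <- Re(cs$S[1, 1, ]); syy <- Re(cs$S[2, 2, ]); sxy <- cs$S[1, 2, ]
  den <- sqrt(sxx * syy)
  v <- ifelse(den > 0, Im(sxy / den), NA_real_)
  attr(v, "freq") <- cs$freq
  v
}

#' Fisher-z average of correlation-like values
#'
#' `tanh(mean(atanh(v)))`; values at or beyond +-1 are clipped to
#' `1 - 1e-12` in magnitude with a warning, `NA`s are dropped.
#'
#' @param values numeric vector with `|v| < 1`
#' @return the Fisher-inverse mean
#' @export
fisher_mean <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) return(NA_real_)
  if (any(abs(values) >= 1)) {
    warning("values with |v| >= 1 clipped")
    values <- pmin(pmax(values, -1 + 1e-12), 1 - 1e-12)
  }
  tanh(mean(atanh(values)))
}

## epoch start rows of a given state (non-excluded), as sample indices
state_epoch_rows <- function(h, fs, state, n_samples) {
  spe <- round(h$epoch_s * fs)
  n_ep <- min(length(h$labels), n_samples %/% spe)
  idx <- which(h$labels[seq_len(n_ep)] == state)
  lapply(idx, function(i) ((i - 1) * spe + 1):(i * spe))
}

#' Per-pair state coherence spectrum (Fisher-averaged over epochs)
#'
#' Imaginary coherency is estimated per 5 s epoch of the requested state and
#' Fisher-z averaged per bin. The pair is stored in canonical orientation
#' (lower id first); swapping the orientation negates every bin.
#'
#' @param rec an `eeg_recording` (typically decimated to 125 Hz)
#' @param h a `hypnogram`
#' @param state brain state label
#' @param pair integer vector of two channel ids
#' @return a `coherence_pair`: list with `pair`, `freq`, `z_inv_values`,
#'   `n_epochs`
#' @export
state_pair_spectrum <- function(rec, h, state, pair) {
  stopifnot(length(pair) == 2)
  pair <- sort(as.integer(pair))
  i <- channel_column(rec, pair[1]); j <- channel_column(rec, pair[2])
  rows <- state_epoch_rows(h, rec$fs, state, nrow(rec$data))
  if (!length(rows)) stop("no non-excluded epochs of state ", state)
  per <- vapply(rows, function(r)
    imaginary_coherency(rec$data[r, i], rec$data[r, j], rec$fs),
    numeric(length(COH_GRID)))
  z <- apply(per, 1, fisher_mean)
  structure(list(pair = pair, freq = COH_GRID, z_inv_values = z,
                 n_epochs = length(rows)),
            class = "coherence_pair")
}

#' All-pairs state coherence spectra in one pass
#'
#' Computes per-epoch Welch spectra once per channel and forms every pairwise
#' imaginary coherency from them, then Fisher-z averages across epochs.
#' Equivalent to calling [state_pair_spectrum()] for each pair, but far
#' cheaper for the full 496-pair set.
#'
#' @param rec an `eeg_recording`
#' @param h a `hypnogram`
#' @param state brain state label
#' @param channels channel ids to include (default: all)
#' @return list of `coherence_pair` objects, canonical orientation, named
#'   `"a-b"`
#' @export
state_coherence_all <- function(rec, h, state, channels = NULL) {
  channels <- sort(as.integer(channels %||% rec$channel_ids))
  cols <- vapply(channels, channel_column, 0L, rec = rec)
  rows <- state_epoch_rows(h, rec$fs, state, nrow(rec$data))
  if (!length(rows)) stop("no non-excluded epochs of state ", state)
  nc <- length(channels); nb <- length(COH_GRID)
  zsum <- array(0, dim = c(nc, nc, nb))
  zn <- array(0L, dim = c(nc, nc, nb))
  for (r in rows) {
    cs <- welch_cross_spectra(rec$data[r, cols, drop = FALSE], rec$fs)
    for (b in seq_len(nb)) {
      Sb <- cs$S[, , b]
      den <- sqrt(outer(Re(diag(Sb)), Re(diag(Sb))))
      ic <- ifelse(den > 0, Im(Sb / den), NA_real_)
      ic <- pmin(pmax(ic, -1 + 1e-12), 1 - 1e-12)
      ok <- !is.na(ic)
      zsum[, , b][ok] <- zsum[, , b][ok] + atanh(ic[ok])
      zn[, , b][ok] <- zn[, , b][ok] + 1L
    }
  }
  out <- list()
  for (a in 1:(nc - 1)) for (b2 in (a + 1):nc) {
    z <- tanh(ifelse(zn[a, b2, ] > 0, zsum[a, b2, ] / zn[a, b2, ], NA_real_))
    key <- paste0(channels[a], "-", channels[b2])
    out[[key]] <- structure(
      list(pair = c(channels[a], channels[b2]), freq = COH_GRID,
           z_inv_values = z, n_epochs = length(rows)),
      class = "coherence_pair")
  }
  out
}

#' Average coherence spectra over a pair selection
#'
#' Distance-group mode: arithmetic mean of the pairs' Fisher-averaged values
#' per bin.
#'
#' @param pairs list of `coherence_pair` objects named `"a-b"` (canonical ids)
#' @param sel a `pair_set` from [pairs_by_threshold()], or a data.frame with
#'   `chan_a`/`chan_b`
#' @return a `group_spectrum`: list with `freq`, `values`, `n_pairs`, `selection`
#' @export
group_average <- function(pairs, sel) {
  pdf <- if (inherits(sel, "pair_set")) sel$pairs else sel
  if (nrow(pdf) == 0) stop("empty selection")
  keys <- paste0(pmin(pdf$chan_a, pdf$chan_b), "-", pmax(pdf$chan_a, pdf$chan_b))
  miss <- setdiff(keys, names(pairs))
  if (length(miss)) stop("pairs missing from input: ", paste(miss, collapse = ", "))
  vals <- rowMeans(vapply(keys, function(k) pairs[[k]]$z_inv_values,
                          numeric(length(COH_GRID))), na.rm = TRUE)
  structure(list(freq = COH_GRID, values = vals, n_pairs = length(keys),
                 selection = if (inherits(sel, "pair_set"))
                   sprintf("%s %g mm", sel$side, sel$threshold_mm) else "custom"),
            class = "group_spectrum")
}

#' Regional coherence spectrum (voltages averaged before coherency)
#'
#' Member-channel voltages of each region are averaged first; imaginary
#' coherency is then estimated between the two regional signals.
#'
#' @param rec an `eeg_recording`
#' @param h a `hypnogram`
#' @param state brain state label
#' @param array an `electrode_array`
#' @param region_a,region_b region group labels (e.g. `"right middle"`)
#' @return a `coherence_pair` with `pair = c(NA, NA)` and a `regions` field
#' @export
region_pair_spectrum <- function(rec, h, state, array, region_a, region_b) {
  ca <- vapply(region_channels(array, region_a), channel_column, 0L, rec = rec)
  cb <- vapply(region_channels(array, region_b), channel_column, 0L, rec = rec)
  xa <- rowMeans(rec$data[, ca, drop = FALSE])
  xb <- rowMeans(rec$data[, cb, drop = FALSE])
  rows <- state_epoch_rows(h, rec$fs, state, nrow(rec$data))
  if (!length(rows)) stop("no non-excluded epochs of state ", state)
  per <- vapply(rows, function(r) imaginary_coherency(xa[r], xb[r], rec$fs),
                numeric(length(COH_GRID)))
  structure(list(pair = c(NA, NA), regions = c(region_a, region_b),
                 freq = COH_GRID, z_inv_values = apply(per, 1, fisher_mean),
                 n_epochs = length(rows)),
            class = "coherence_pair")
}

#' @export
print.coherence_pair <- function(x, ...) {
  who <- if (!is.null(x$regions)) paste(x$regions, collapse = " vs ")
         else paste(x$pair, collapse = "-")
  cat(sprintf("<coherence_pair> %s: 99 bins over %d epochs\n", who, x$n_epochs))
  invisible(x)
}

#' @export
print.group_spectrum <- function(x, ...) {
  cat(sprintf("<group_spectrum> %s: %d pairs\n", x$selection, x$n_pairs))
  invisible(x)
}
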