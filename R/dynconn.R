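#' Coherogram grids: 11 spindle-band components; 2000 time points at 1 ms
#' steps from 500 ms before to 1500 ms after spindle start
#' @export
COHEROGRAM_FREQS <- seq(12, 17, by = 0.5)

#' @rdname COHEROGRAM_FREQS
#' @export
COHEROGRAM_TIMES <- seq(-0.5, 1.4995, by = 0.001)

#' Event-locked complex Morlet time-frequency coefficients
#'
#' Convolves the trace with complex Morlet wavelets (7 cycles, truncated at
#' +-3 SD of the Gaussian envelope) at 11 components from 12 to 17 Hz, in a
#' window from 500 ms before to 1500 ms after each event start, sampled onto
#' a 1 ms grid (2000 time points). Events whose padded window falls outside
#' the recording are dropped (listed in the `dropped` attribute).
#'
#' @param x single-channel trace
#' @param fs sampling rate, Hz (>= 2x the top frequency)
#' @param event_starts_s event (spindle) start times in seconds
#' @param freqs wavelet centre frequencies (default 12-17 Hz by 0.5)
#' @param cycles wavelet cycle width (default 7)
#' @param times output time grid relative to event start (default
#'   -500..+1499 ms by 1 ms)
#' @return complex array `trials x freq x time` with attributes `freqs`,
#'   `times`, `dropped`
#' @export
morlet_tfr <- function(x, fs, event_starts_s, freqs = COHEROGRAM_FREQS,
                       cycles = 7, times = COHEROGRAM_TIMES) {
  if (fs < 2 * max(freqs)) stop("fs below twice the top frequency")
  pad <- 3 * cycles / (2 * pi * min(freqs))        # widest wavelet half-width
  lo <- min(times) - pad; hi <- max(times) + pad
  seg_len <- floor((hi - lo) * fs) + 1L
  n <- length(x)
  keep <- logical(length(event_starts_s))
  segs <- list()
  for (k in seq_along(event_starts_s)) {
    i0 <- floor((event_starts_s[k] + lo) * fs) + 1L
    if (i0 >= 1 && i0 + seg_len - 1 <= n) {
      keep[k] <- TRUE
      segs[[length(segs) + 1]] <- x[i0:(i0 + seg_len - 1)]
    }
  }
  if (length(segs) < 1) stop("no event window fully inside the recording")
  seg_t <- lo + (seq_len(seg_len) - 1) / fs        # time rel. event start
  out <- array(0 + 0i, dim = c(length(segs), length(freqs), length(times)))
  nfft <- stats::nextn(seg_len + ceiling(2 * pad * fs) + 1, 2)
  segF <- vapply(segs, function(s) stats::fft(c(s, numeric(nfft - seg_len))),
                 complex(nfft))
  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    sig <- cycles / (2 * pi * f)
    tw <- seq(-3 * sig, 3 * sig, by = 1 / fs)
    w <- exp(2i * pi * f * tw) * exp(-tw^2 / (2 * sig^2))
    w <- w / sqrt(sum(Mod(w)^2))
    wF <- stats::fft(c(w, complex(real = numeric(nfft - length(w)))))
    half <- (length(w) - 1) / 2
    for (tr in seq_along(segs)) {
      conv <- stats::fft(segF[, tr] * wF, inverse = TRUE) / nfft
      centred <- conv[(half + 1):(half + seg_len)]   # align to segment times
      out[tr, fi, ] <- stats::approx(seg_t, Re(centred), xout = times)$y +
        1i * stats::approx(seg_t, Im(centred), xout = times)$y
    }
  }
  attr(out, "freqs") <- freqs
  attr(out, "times") <- times
  attr(out, "dropped") <- which(!keep)
  out
}

#' Event-locked imaginary coherogram from two channels' trial coefficients
#'
#' Per time-frequency bin, the imaginary part of the trial-summed coherency
#' `sum(Wx conj(Wy)) / sqrt(sum|Wx|^2 sum|Wy|^2)`.
#'
#' @param tfr_x,tfr_y complex `trials x freq x time` arrays from
#'   [morlet_tfr()] with equal trial counts (>= 2)
#' @return a `coherogram`: list with `freq`, `times`, `values`
#'   (freq x time matrix in `[-1, 1]`), `n_trials`
#' @export
event_coherogram <- function(tfr_x, tfr_y) {
  if (!all(dim(tfr_x) == dim(tfr_y))) stop("dimension mismatch")
  if (dim(tfr_x)[1] < 2) stop("need at least 2 trials")
  num <- apply(tfr_x * Conj(tfr_y), c(2, 3), sum)
  sxx <- apply(Mod(tfr_x)^2, c(2, 3), sum)
  syy <- apply(Mod(tfr_y)^2, c(2, 3), sum)
  den <- sqrt(sxx * syy)
  vals <- matrix(0, nrow = dim(tfr_x)[2], ncol = dim(tfr_x)[3])
  ok <- den > 0
  vals[ok] <- Im(num[ok] / den[ok])
  structure(list(freq = attr(tfr_x, "freqs"), times = attr(tfr_x, "times"),
                 values = vals, n_trials = dim(tfr_x)[1],
                 zero_denominator_bins = sum(!ok)),
            class = "coherogram")
}

#' Average a list of coherograms bin-wise
#'
#' @param cgs list of `coherogram` objects on one grid
#' @return a `coherogram` (values averaged; `n_trials` from the first)
#' @export
average_coherograms <- function(cgs) {
  stopifnot(length(cgs) >= 1)
  v <- Reduce(`+`, lapply(cgs, `[[`, "values")) / length(cgs)
  out <- cgs[[1]]
  out$values <- v
  out$n_pairs <- length(cgs)
  out
}

#' High-connectivity bin statistic of a coherogram
#'
#' Finds the maximum of the absolute imaginary coherence over all
#' time-frequency bins and counts the bins exceeding `fraction` of that
#' maximum; also reports the mean frequency of those bins. The count is
#' invariant under global scaling of the coherogram.
#'
#' @param cg a `coherogram` (typically pair-averaged per animal)
#' @param fraction threshold as a fraction of the maximum (default 0.70)
#' @return list with `max_value`, `n_supra_bins`, `mean_freq_hz`
#' @export
high_connectivity <- function(cg, fraction = 0.70) {
  a <- abs(cg$values)
  M <- max(a)
  if (M == 0)
    return(list(max_value = 0, n_supra_bins = 0L, mean_freq_hz = NA_real_,
                degenerate = TRUE))
  supra <- a > fraction * M
  fmat <- matrix(cg$freq, nrow = nrow(a), ncol = ncol(a))
  list(max_value = M, n_supra_bins = sum(supra),
       mean_freq_hz = mean(fmat[supra]))
}

#' Spindle-locked pair-averaged coherogram for one animal
#'
#' Computes Morlet coefficients once per channel involved in the selected
#' pairs, forms each pair's imaginary coherogram, and averages across pairs.
#'
#' @param rec an `eeg_recording` (undecimated or >= 125 Hz)
#' @param spindle_starts_s spindle start times (s) used as trial anchors
#' @param pairs data.frame with `chan_a`/`chan_b` columns (e.g.
#'   `pairs_by_threshold(...)$pairs`)
#' @param ... passed to [morlet_tfr()]
#' @return a `coherogram` averaged over pairs
#' @export
spindle_coherogram <- function(rec, spindle_starts_s, pairs, ...) {
  pdf <- if (inherits(pairs, "pair_set")) pairs$pairs else pairs
  chans <- sort(unique(c(pdf$chan_a, pdf$chan_b)))
  tfrs <- lapply(chans, function(ch)
    morlet_tfr(channel_signal(rec, ch), rec$fs, spindle_starts_s, ...))
  names(tfrs) <- as.character(chans)
  cgs <- lapply(seq_len(nrow(pdf)), function(i)
    event_coherogram(tfrs[[as.character(pdf$chan_a[i])]],
                     tfrs[[as.character(pdf$chan_b[i])]]))
  average_coherograms(cgs)
}

#' @export
print.coherogram <- function(x, ...) {
  cat(sprintf("<coherogram> %d x %d bins, %d trials\n",
              nrow(x$values), ncol(x$values), x$n_trials))
  invisible(x)
}
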