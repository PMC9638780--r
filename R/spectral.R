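#' Band scheme for summary power
#'
#' Default bands: delta 1-4, theta 5-10, sigma 12-17, beta 17-30,
#' gamma 30-48 Hz. Band edges are inclusive.
#'
#' @param bands named list of `c(lo, hi)` pairs in Hz
#' @return a named list of class `band_scheme`
#' @export
band_scheme <- function(bands = list(delta = c(1, 4), theta = c(5, 10),
                                     sigma = c(12, 17), beta = c(17, 30),
                                     gamma = c(30, 48))) {
  if (!length(bands)) stop("empty band scheme")
  for (b in bands)
    if (length(b) != 2 || b[1] >= b[2]) stop("bands must be c(lo, hi), lo < hi")
  structure(bands, class = "band_scheme")
}

## closed-form sine tapers (unit energy up to N/(N+1)); k-th taper, length n
sine_tapers <- function(n, k) {
  t(vapply(seq_len(k), function(j) sqrt(2 / (n + 1)) * sin(pi * j * seq_len(n) / (n + 1)),
           numeric(n)))
}

PSD_GRID <- seq(0.2, 48, by = 0.2)  # 240 bins mandated by the analysis

#' Multitaper log-power spectrum of one 5 s epoch
#'
#' Sine-taper multitaper estimate (7 tapers) evaluated on the fixed
#' 0.2-48 Hz grid in 0.2 Hz steps (240 bins); values are log10 power per bin.
#' For 5 s epochs the periodogram's native resolution is exactly 0.2 Hz, so
#' no interpolation is involved; other epoch lengths are linearly
#' interpolated onto the grid.
#'
#' @param segment single-channel trace of one epoch (microvolts)
#' @param fs sampling rate in Hz
#' @param n_tapers number of sine tapers (default 7)
#' @param epoch_s nominal epoch length; `length(segment)` must equal
#'   `epoch_s * fs`
#' @return an object of class `psd`: list with `freq` (240 bin centres) and
#'   `values` (log10 power), plus taper metadata
#' @export
epoch_psd <- function(segment, fs, n_tapers = 7, epoch_s = 5) {
  n <- length(segment)
  if (n != round(epoch_s * fs))
    stop("wrong segment length: expected ", round(epoch_s * fs), ", got ", n)
  if (any(!is.finite(segment))) stop("non-finite samples")
  x <- segment - mean(segment)
  tap <- sine_tapers(n, n_tapers)
  nf <- floor(n / 2)
  p <- rowMeans(vapply(seq_len(n_tapers), function(j) {
    X <- stats::fft(x * tap[j, ])
    Mod(X[2:(nf + 1)])^2 / fs
  }, numeric(nf)))
  fr <- (1:nf) * fs / n
  vals <- stats::approx(fr, p, xout = PSD_GRID, rule = 2)$y
  structure(list(freq = PSD_GRID, values = log10(pmax(vals, .Machine$double.xmin)),
                 n_tapers = n_tapers, epoch_s = epoch_s),
            class = "psd")
}

#' Per-epoch spectra of one channel under a hypnogram
#'
#' @param rec an `eeg_recording`
#' @param h a `hypnogram`
#' @param channel channel id
#' @return list of per-epoch `psd` objects (NULL for EXCLUDED epochs)
#' @export
epoch_psds <- function(rec, h, channel) {
  x <- channel_signal(rec, channel)
  spe <- round(h$epoch_s * rec$fs)
  n_ep <- min(length(h$labels), length(x) %/% spe)
  lapply(seq_len(n_ep), function(i) {
    if (h$labels[i] == "EXCLUDED") return(NULL)
    epoch_psd(x[((i - 1) * spe + 1):(i * spe)], rec$fs, epoch_s = h$epoch_s)
  })
}

#' Average log-power spectrum over one brain state
#'
#' Arithmetic mean of log10 spectra across the state's non-excluded epochs.
#'
#' @param psds list of per-epoch `psd` objects (NULL entries ignored)
#' @param h the matching `hypnogram`
#' @param state `"WAKE"`, `"NREM"` or `"REM"`
#' @return a `psd`
#' @export
state_average_psd <- function(psds, h, state) {
  stopifnot(inherits(h, "hypnogram"))
  idx <- which(h$labels[seq_along(psds)] == state &
               !vapply(psds, is.null, TRUE))
  if (!length(idx)) stop("no epochs of state ", state)
  vals <- rowMeans(vapply(psds[idx], function(p) p$values,
                          numeric(length(PSD_GRID))))
  structure(list(freq = PSD_GRID, values = vals,
                 n_tapers = psds[[idx[1]]]$n_tapers,
                 epoch_s = psds[[idx[1]]]$epoch_s, n_epochs = length(idx)),
            class = "psd")
}

#' Band averages of a spectrum
#'
#' Mean of the bins whose centre lies in `[lo, hi]` (inclusive).
#'
#' @param psd a `psd`
#' @param scheme a `band_scheme`
#' @return named numeric vector of band means
#' @export
band_average <- function(psd, scheme = band_scheme()) {
  vapply(scheme, function(b) {
    sel <- psd$freq >= b[1] & psd$freq <= b[2]
    if (!any(sel)) stop("band outside PSD grid")
    mean(psd$values[sel])
  }, 0)
}

#' @export
print.psd <- function(x, ...) {
  cat(sprintf("<psd> %d bins %.1f-%.1f Hz, %d tapers\n",
              length(x$freq), min(x$freq), max(x$freq), x$n_tapers))
  invisible(x)
}
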