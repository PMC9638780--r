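#' Spike-and-wave discharge detector parameters
#'
#' @param window_s sliding PSD window length (s)
#' @param step_s window step (s)
#' @param band fundamental search band, Hz (theta-range discharges)
#' @param n_harmonics number of harmonics checked above the fundamental
#' @param prominence harmonic peak / local-median power ratio required
#' @param amp_floor_uV minimum absolute window amplitude
#' @param min_dur_s minimum event duration after merging
#' @param merge_gap_s windows closer than this merge into one event
#' @return a list of class `swd_params`
#' @export
swd_params <- function(window_s = 1.0, step_s = 0.5, band = c(5, 10),
                       n_harmonics = 2, prominence = 3, amp_floor_uV = 200,
                       min_dur_s = 1.0, merge_gap_s = 0.5) {
  stopifnot(window_s > 0, step_s > 0, prominence > 0, amp_floor_uV > 0,
            min_dur_s > 0, merge_gap_s >= 0, band[1] > 0, band[2] > band[1])
  structure(list(window_s = window_s, step_s = step_s, band = band,
                 n_harmonics = n_harmonics, prominence = prominence,
                 amp_floor_uV = amp_floor_uV, min_dur_s = min_dur_s,
                 merge_gap_s = merge_gap_s),
            class = "swd_params")
}

#' Harmonic-peak score of a power spectrum
#'
#' The fundamental is the maximal peak inside `band`; the score is the
#' minimum over harmonics `k = 2..n_harmonics+1` of the peak power at
#' `k * f0` (within +-1 bin) divided by the local median power (+-2 Hz
#' neighbourhood). A periodic discharge scores high; a pure sinusoid or
#' broadband noise does not.
#'
#' @param psd numeric vector of power values
#' @param freqs matching frequency grid (uniform spacing)
#' @param band fundamental search band `c(lo, hi)` in Hz
#' @param n_harmonics number of harmonics checked
#' @return list with `fundamental_hz` and `score`
#' @export
harmonic_score <- function(psd, freqs, band = c(5, 10), n_harmonics = 2) {
  if (band[1] < min(freqs) || band[2] > max(freqs))
    stop("band outside PSD grid")
  if (band[2] * (n_harmonics + 1) > max(freqs))
    stop("PSD grid too short for requested harmonics")
  df <- freqs[2] - freqs[1]
  in_band <- which(freqs >= band[1] & freqs <= band[2])
  f0 <- freqs[in_band[which.max(psd[in_band])]]
  score <- Inf
  for (k in 2:(n_harmonics + 1)) {
    fk <- k * f0
    peak <- max(psd[abs(freqs - fk) <= df + 1e-9])
    ## local floor: +-4 Hz neighbourhood excluding the peak bins themselves,
    ## so broad genuine harmonics do not inflate their own reference level
    nb <- psd[abs(freqs - fk) <= 4 + 1e-9 & abs(freqs - fk) > df + 1e-9]
    if (!length(nb)) nb <- psd[abs(freqs - fk) <= 4 + 1e-9]
    score <- min(score, peak / max(stats::median(nb), .Machine$double.xmin))
  }
  list(fundamental_hz = f0, score = score)
}

## merge passing-window intervals: union with gap tolerance
merge_intervals <- function(starts, ends, gap) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out <- list()
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me + gap) me <- max(me, ends[i])
    else { out[[length(out) + 1]] <- c(ms, me); ms <- starts[i]; me <- ends[i] }
  }
  out[[length(out) + 1]] <- c(ms, me)
  do.call(rbind, out)
}

#' Detect spike-and-wave discharges on one channel
#'
#' Slides a PSD window over the trace; windows whose peak amplitude reaches
#' the floor and whose harmonic score reaches the prominence factor are
#' marked, overlapping or near (<= merge gap) marked windows merge, and
#' events shorter than the minimum duration are dropped. The harmonic score
#' is a power ratio, so detection is amplitude-scale covariant above the
#' floor.
#'
#' @param x single-channel trace in microvolts
#' @param fs sampling rate, Hz
#' @param params an [swd_params()] list
#' @param channel channel id recorded on the events (default `NA`:
#'   recording-wide)
#' @return an `interval_events` table with `fundamental_hz`, `score`,
#'   `peak_uV` and `duration_s` properties
#' @export
detect_swd <- function(x, fs, params = swd_params(), channel = NA_integer_) {
  win <- round(params$window_s * fs)
  if (length(x) < win) stop("signal shorter than one window")
  if (fs / 2 < params$band[2] * (params$n_harmonics + 1))
    stop("fs too low for requested harmonics")
  step <- max(1L, round(params$step_s * fs))
  starts <- seq(1L, length(x) - win + 1L, by = step)
  fr <- (1:floor(win / 2)) * fs / win
  hits <- list()
  for (s in starts) {
    seg <- x[s:(s + win - 1)]
    if (max(abs(seg)) < params$amp_floor_uV) next
    X <- stats::fft(seg - mean(seg))
    psd <- Mod(X[2:(floor(win / 2) + 1)])^2
    hs <- harmonic_score(psd, fr, params$band, params$n_harmonics)
    if (hs$score >= params$prominence)
      hits[[length(hits) + 1]] <- c((s - 1) / fs, (s - 1 + win) / fs,
                                    hs$fundamental_hz, hs$score)
  }
  if (!length(hits)) return(empty_events())
  hm <- do.call(rbind, hits)
  ## merge near windows only when their fundamentals agree: a discharge has
  ## one fundamental, and merging across distinct trains would corrupt the
  ## whole-event spectrum used for validation
  o <- order(hm[, 1])
  hm <- hm[o, , drop = FALSE]
  merged <- NULL
  cur <- hm[1, 1:2]; cur_f <- hm[1, 3]
  for (i in seq_len(nrow(hm))[-1]) {
    if (hm[i, 1] <= cur[2] + params$merge_gap_s &&
        abs(hm[i, 3] - cur_f) <= 1) {
      cur[2] <- max(cur[2], hm[i, 2])
    } else {
      merged <- rbind(merged, cur)
      cur <- hm[i, 1:2]; cur_f <- hm[i, 3]
    }
  }
  merged <- rbind(merged, cur)
  ev <- lapply(seq_len(nrow(merged)), function(i) {
    s <- merged[i, 1]; e <- merged[i, 2]
    if (e - s < params$min_dur_s) return(NULL)
    inw <- hm[, 1] >= s - 1e-9 & hm[, 2] <= e + 1e-9
    seg <- x[(round(s * fs) + 1):min(round(e * fs), length(x))]
    ## whole-event validation: harmonic peaks must persist in the
    ## Welch-averaged event spectrum, not just single windows
    wp <- welch_psd(seg, fs, nperseg = win)
    hv <- harmonic_score(wp$psd, wp$freq, params$band, params$n_harmonics)
    if (hv$score < params$prominence) return(NULL)
    interval_events(kind = "swd", channel = channel, start_s = s, end_s = e,
                    fundamental_hz = hv$fundamental_hz,
                    score = hv$score,
                    peak_uV = max(abs(seg)), duration_s = e - s)
  })
  do.call(bind_events, ev)
}

## Welch-averaged one-sided periodogram (Hann window, 50% overlap)
welch_psd <- function(x, fs, nperseg) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  hop <- max(1L, nperseg %/% 2)
  starts <- seq(1, n - nperseg + 1, by = hop)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  nf <- floor(nperseg / 2)
  p <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1)]
    p <- p + Mod(stats::fft((seg - mean(seg)) * win)[2:(nf + 1)])^2
  }
  list(freq = (1:nf) * fs / nperseg, psd = p / length(starts))
}
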