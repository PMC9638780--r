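#' Sleep-spindle detector parameters
#'
#' Defaults follow the envelope-threshold scheme: 12-17 Hz band, event length
#' 0.2-3 s, minimal inter-event gap 0.2 s, amplitude window 25-750 uV,
#' boundary threshold 1.5 SD and detection threshold 3 SD of the NREM
#' envelope, noise exclusion at >= 35 SD. Thresholds are applied as
#' `mean + k * SD` of the smoothed NREM envelope.
#'
#' @param band spindle band in Hz
#' @param min_dur_s,max_dur_s event duration window (s)
#' @param min_gap_s events closer than this merge
#' @param amp_min_uV,amp_max_uV peak-to-trough amplitude window
#' @param boundary_sd,detect_sd,noise_sd envelope thresholds in SD units
#' @param smooth_s envelope moving-average span (s), default 25 ms
#' @return a list of class `spindle_params`
#' @export
spindle_params <- function(band = c(12, 17), min_dur_s = 0.2, max_dur_s = 3.0,
                           min_gap_s = 0.2, amp_min_uV = 25, amp_max_uV = 750,
                           boundary_sd = 1.5, detect_sd = 3.0, noise_sd = 35,
                           smooth_s = 0.025) {
  stopifnot(min_dur_s > 0, min_dur_s < max_dur_s,
            boundary_sd < detect_sd, detect_sd < noise_sd,
            amp_min_uV < amp_max_uV)
  structure(list(band = band, min_dur_s = min_dur_s, max_dur_s = max_dur_s,
                 min_gap_s = min_gap_s, amp_min_uV = amp_min_uV,
                 amp_max_uV = amp_max_uV, boundary_sd = boundary_sd,
                 detect_sd = detect_sd, noise_sd = noise_sd,
                 smooth_s = smooth_s),
            class = "spindle_params")
}

## zero-phase FIR band-pass: windowed-sinc design, group delay removed exactly
fir_bandpass <- function(x, fs, lo, hi, transition = 1) {
  ord <- ceiling(3.3 * fs / transition / 2) * 2   # Hamming-window rule
  b <- signal::fir1(ord, c(lo, hi) / (fs / 2), type = "pass")
  y <- signal::fftfilt(b, c(x, numeric(ord)))
  y[(ord / 2 + 1):(ord / 2 + length(x))]
}

## sample mask from an epoch-level NREM mask
samples_in_mask <- function(mask, spe, n) {
  out <- rep(FALSE, n)
  for (i in which(mask)) {
    lo <- (i - 1) * spe + 1
    if (lo > n) break
    out[lo:min(i * spe, n)] <- TRUE
  }
  out
}

#' Detect sleep spindles on one channel during NREM
#'
#' The trace is band-passed (zero-phase FIR), the analytic-amplitude envelope
#' smoothed with a short moving average, and candidate events found where the
#' envelope reaches `mean + detect_sd * SD` of the NREM envelope; boundaries
#' extend to the surrounding `mean + boundary_sd * SD` crossings. Candidates
#' closer than the minimal gap merge; events outside the duration or
#' amplitude windows, or reaching the noise threshold, are dropped. All
#' returned events lie wholly within NREM-masked time.
#'
#' @param x single-channel trace in microvolts
#' @param fs sampling rate, Hz (must exceed twice the band top)
#' @param nrem_mask logical vector, one entry per epoch, `TRUE` for NREM
#' @param params a [spindle_params()] list
#' @param epoch_s epoch length (default 5)
#' @param channel channel id recorded on the events
#' @return an `interval_events` table with `duration_s`, `amp_uV`
#'   (peak-to-trough), `peak_freq_hz` and `band_power` properties
#' @export
detect_spindles <- function(x, fs, nrem_mask, params = spindle_params(),
                            epoch_s = 5, channel = NA_integer_) {
  if (fs < 2 * params$band[2]) stop("fs below twice the band top")
  if (!any(nrem_mask)) stop("empty NREM mask")
  spe <- round(epoch_s * fs)
  smask <- samples_in_mask(nrem_mask, spe, length(x))
  bp <- fir_bandpass(x, fs, params$band[1], params$band[2])
  env <- moving_average(Mod(analytic_signal(bp)),
                        max(1L, round(params$smooth_s * fs)))
  mu <- mean(env[smask]); sdv <- stats::sd(env[smask])
  t_detect <- mu + params$detect_sd * sdv
  t_bound <- mu + params$boundary_sd * sdv
  t_noise <- mu + params$noise_sd * sdv
  envm <- env
  envm[!smask] <- 0
  above <- envm >= t_bound
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cand <- which(r$values)
  keep <- vapply(cand, function(k) any(envm[starts[k]:ends[k]] >= t_detect), TRUE)
  cand <- cand[keep]
  if (!length(cand)) return(empty_events())
  merged <- merge_intervals(starts[cand], ends[cand],
                            gap = round(params$min_gap_s * fs))
  ev <- lapply(seq_len(nrow(merged)), function(i) {
    a <- merged[i, 1]; b <- merged[i, 2]
    dur <- (b - a + 1) / fs
    ## the length window applies to the detection-threshold crossing span:
    ## the 1.5 SD boundary extent is widened by band-limited smearing, while
    ## the 3 SD core tracks the true burst duration
    core <- which(envm[a:b] >= t_detect)
    core_dur <- (max(core) - min(core) + 1) / fs
    if (core_dur < params$min_dur_s || core_dur > params$max_dur_s) return(NULL)
    seg <- bp[a:b]
    amp <- max(seg) - min(seg)
    if (amp < params$amp_min_uV || amp > params$amp_max_uV) return(NULL)
    if (max(env[a:b]) >= t_noise) return(NULL)
    nfft <- max(length(seg), as.integer(2 * fs))   # >= 0.5 Hz resolution
    X <- Mod(stats::fft(c(seg - mean(seg), numeric(nfft - length(seg)))))^2
    fr <- (0:(nfft - 1)) * fs / nfft
    inb <- fr >= params$band[1] & fr <= params$band[2]
    interval_events(kind = "spindle", channel = channel,
                    start_s = (a - 1) / fs, end_s = b / fs,
                    duration_s = dur, amp_uV = amp,
                    peak_freq_hz = fr[inb][which.max(X[inb])],
                    band_power = mean(seg^2))
  })
  do.call(bind_events, ev)
}

## minimal union-find
uf_new <- function(n) seq_len(n)
uf_find <- function(p, i) { while (p[i] != i) i <- p[i]; i }
uf_union <- function(p, i, j) { p[uf_find(p, i)] <- uf_find(p, j); p }

#' Group spindles detected on multiple nearby electrodes
#'
#' Spindles on different channels whose electrodes lie within `radius_mm` of
#' each other and whose intervals overlap in time are merged into one
#' multi-electrode spindle by transitive closure. Returns the number of
#' groups spanning at least two electrodes and the mean number of distinct
#' electrodes among those groups.
#'
#' @param events an `interval_events` table of spindles across channels
#' @param array an `electrode_array`
#' @param radius_mm grouping radius (default 2 mm)
#' @return list with `n_multielectrode`, `mean_electrodes` and
#'   `group_id` (per input event)
#' @export
multisite_spindles <- function(events, array, radius_mm = 2) {
  if (nrow(events) == 0)
    return(list(n_multielectrode = 0L, mean_electrodes = NA_real_,
                group_id = integer()))
  if (any(!events$channel %in% array$id)) stop("unknown channel id")
  d <- pairwise_distances(array)
  key <- as.character(events$channel)
  n <- nrow(events)
  p <- uf_new(n)
  o <- order(events$start_s)
  for (ii in seq_len(n - 1)) {
    i <- o[ii]
    for (jj in (ii + 1):n) {
      j <- o[jj]
      if (events$start_s[j] >= events$end_s[i]) break
      if (key[i] != key[j] && d[key[i], key[j]] <= radius_mm)
        p <- uf_union(p, i, j)
    }
  }
  root <- vapply(seq_len(n), function(i) uf_find(p, i), 0L)
  sizes <- tapply(events$channel, root, function(ch) length(unique(ch)))
  multi <- sizes[sizes >= 2]
  list(n_multielectrode = length(multi),
       mean_electrodes = if (length(multi)) mean(multi) else NA_real_,
       group_id = match(root, sort(unique(root))))
}
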