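#' Simulation parameters for the synthetic EEG generator
#'
#' Defaults describe a 6 h, 1 kHz, 32-channel skull-surface recording with
#' wake/NREM/REM dwell structure, 1/f background, NREM delta and spindle
#' content, REM theta, wake desynchronization, spike-and-wave discharge
#' trains during wake, movement artifacts above 750 uV, and distance-
#' dependent phase-lagged coupling injected as per-region shared sources.
#'
#' @param fs sampling rate, Hz
#' @param duration_s recording length, s (tests use short durations)
#' @param epoch_s scoring epoch, s
#' @param seed integer seed; fixed seed gives bit-identical output
#' @param dwell_mean_s mean bout dwell per state, s
#' @param p_nrem_to_rem probability that an ending NREM bout enters REM
#' @param bg_exponent background spectral exponent (power ~ 1/f^exponent)
#' @param bg_rms_uV background RMS per state, uV
#' @param osc per-state independent narrowband oscillator specs
#'   (`freq = c(lo, hi)`, `rms` uV)
#' @param coupling per-band shared-source specs: `band`, source `rms` (uV),
#'   injection `gain` in \[0, 1\], per-channel `lag_step_ms`, and the state
#'   the source is active in
#' @param spindle spindle event spec: rate per NREM minute, duration range,
#'   carrier frequency range, peak amplitude, gain on neighbouring channels
#' @param swd discharge event spec: rate per wake minute, fundamental range,
#'   number of harmonics, amplitude, duration range
#' @param artifact movement-artifact spec: rate per wake minute, amplitude
#'   (> 750 uV), duration
#' @param accel_sd accelerometer noise SD per state (a.u.)
#' @return a list of class `sim_params`
#' @export
sim_params <- function(fs = 1000, duration_s = 21600, epoch_s = 5, seed = 1,
                       dwell_mean_s = c(WAKE = 180, NREM = 160, REM = 70),
                       p_nrem_to_rem = 0.35,
                       bg_exponent = 2,
                       bg_rms_uV = c(WAKE = 40, NREM = 55, REM = 45),
                       osc = list(
                         NREM = list(freq = c(1, 4), rms = 80),
                         REM = list(freq = c(5, 10), rms = 50)),
                       coupling = list(
                         sigma = list(band = c(12, 17), rms = 4, gain = 0.7,
                                      lag_step_ms = 2, state = "NREM"),
                         delta = list(band = c(1, 4), rms = 20, gain = 0.5,
                                      lag_step_ms = 4, state = "NREM"),
                         theta = list(band = c(5, 10), rms = 12, gain = 0.5,
                                      lag_step_ms = 3, state = "REM")),
                       spindle = list(rate_per_min = 3, dur_range_s = c(0.4, 1.2),
                                      freq_range_hz = c(12, 16), amp_uV = 100,
                                      group_gain = 0.8, lag_step_ms = 2),
                       swd = list(rate_per_min = 0.25, fund_range_hz = c(6, 9),
                                  n_harmonics = 3, amp_uV = 350,
                                  dur_range_s = c(2, 5)),
                       artifact = list(rate_per_min = 0.2, amp_uV = 900,
                                       dur_s = 0.2),
                       accel_sd = c(WAKE = 1.0, NREM = 0.1, REM = 0.02)) {
  stopifnot(all(dwell_mean_s > 0), all(bg_rms_uV >= 0),
            spindle$rate_per_min >= 0, swd$rate_per_min >= 0,
            artifact$rate_per_min >= 0, duration_s >= epoch_s)
  for (cp in coupling)
    stopifnot(cp$gain >= 0, cp$gain <= 1, cp$lag_step_ms >= 0)
  structure(list(fs = fs, duration_s = duration_s, epoch_s = epoch_s,
                 seed = as.integer(seed), dwell_mean_s = dwell_mean_s,
                 p_nrem_to_rem = p_nrem_to_rem, bg_exponent = bg_exponent,
                 bg_rms_uV = bg_rms_uV, osc = osc, coupling = coupling,
                 spindle = spindle, swd = swd, artifact = artifact,
                 accel_sd = accel_sd),
            class = "sim_params")
}

#' Genotype presets for cohort simulation
#'
#' The mutant preset encodes the qualitative signature under study: longer
#' (hence, over a fixed recording, fewer) wake and NREM bouts, attenuated
#' spindle-band coupling between nearby channels, and a higher discharge
#' rate. The control preset is the identity.
#'
#' @param name `"control"` or `"mutant"`
#' @return a list of class `genotype_preset` with positive multipliers
#'   `dwell_mult` (per state), `coupling_atten` (sigma-band shared-source and
#'   cross-channel spindle gain), `swd_rate_mult`
#' @export
genotype_preset <- function(name = c("control", "mutant")) {
  name <- match.arg(name)
  if (name == "control")
    p <- list(name = name, dwell_mult = c(WAKE = 1, NREM = 1, REM = 1),
              coupling_atten = 1, swd_rate_mult = 1)
  else
    p <- list(name = name, dwell_mult = c(WAKE = 1.6, NREM = 1.6, REM = 1),
              coupling_atten = 0.45, swd_rate_mult = 6)
  stopifnot(all(unlist(p[-1]) > 0))
  structure(p, class = "genotype_preset")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)))
  set.seed(seed)
  force(code)
}

#' Sample a semi-Markov brain-state sequence
#'
#' Geometric dwell times at epoch resolution with state-specific means
#' (scaled by the preset); wake is followed by NREM, NREM by REM with the
#' configured probability (otherwise wake), REM only by wake — so REM is
#' entered only from NREM.
#'
#' @param params a [sim_params()] list
#' @param preset a [genotype_preset()]
#' @param duration_s override the configured duration
#' @return list with `hypnogram` and `bouts` (data.frame `state`,
#'   `start_epoch`, `n_epochs`; the final bout is truncated at the recording
#'   end)
#' @export
sample_state_sequence <- function(params, preset = genotype_preset("control"),
                                  duration_s = params$duration_s) {
  n_ep <- floor(duration_s / params$epoch_s)
  if (n_ep < 1) stop("duration shorter than one epoch")
  mean_ep <- params$dwell_mean_s * preset$dwell_mult[names(params$dwell_mean_s)] /
    params$epoch_s
  if (any(!is.finite(mean_ep)) || any(mean_ep <= 0))
    stop("zero-probability transition configuration")
  with_seed(derive_seed(params$seed, 1), {
    labels <- character(0)
    bouts <- list()
    state <- "WAKE"
    while (length(labels) < n_ep) {
      len <- stats::rgeom(1, prob = min(1, 1 / mean_ep[[state]])) + 1L
      len <- min(len, n_ep - length(labels))
      bouts[[length(bouts) + 1]] <-
        data.frame(state = state, start_epoch = length(labels) + 1L,
                   n_epochs = len)
      labels <- c(labels, rep(state, len))
      state <- switch(state,
        WAKE = "NREM",
        NREM = if (stats::runif(1) < params$p_nrem_to_rem) "REM" else "WAKE",
        REM = "WAKE")
    }
    list(hypnogram = hypnogram(labels, params$epoch_s),
         bouts = do.call(rbind, bouts))
  })
}

## FFT-shaped 1/f^exponent noise, unit RMS
pink_noise <- function(n, fs, exponent) {
  nf <- n %/% 2
  f <- (1:nf) * fs / n
  amp <- f^(-exponent / 2)
  ph <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  full <- c(0, spec, if (n %% 2 == 0) Conj(rev(spec[-nf])) else Conj(rev(spec)))
  x <- Re(stats::fft(full, inverse = TRUE))
  x / stats::sd(x)
}

## brick-wall band-limited Gaussian noise, unit RMS
band_noise <- function(n, fs, band) {
  nf <- n %/% 2
  f <- (1:nf) * fs / n
  amp <- as.numeric(f >= band[1] & f <= band[2])
  ph <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  full <- c(0, spec, if (n %% 2 == 0) Conj(rev(spec[-nf])) else Conj(rev(spec)))
  x <- Re(stats::fft(full, inverse = TRUE))
  x / stats::sd(x)
}

## shift a signal right by `lag` samples (zero-padded)
lag_shift <- function(x, lag) {
  if (lag <= 0) return(x)
  c(numeric(lag), x[seq_len(length(x) - lag)])
}

#' Synthesize a multi-channel EEG recording with known ground truth
#'
#' Builds, per channel, 1/f background scaled per state, state-dependent
#' narrowband oscillators, per-region shared band-limited sources injected
#' with per-channel lags (so imaginary coherency between nearby channels is
#' nonzero by construction, while zero-lag mixing alone would contribute
#' none), planted spindles (Hann-enveloped 12-17 Hz bursts, co-occurring on
#' channels within 2 mm of the seed electrode), spike-and-wave discharges
#' (harmonic trains with square envelopes during wake), and biphasic
#' movement artifacts exceeding 750 uV. The accelerometer trace is quiet in
#' NREM/REM and variable during wake.
#'
#' @param hyp a `hypnogram` (or the list from [sample_state_sequence()])
#' @param array an `electrode_array`
#' @param params a [sim_params()] list
#' @param preset a [genotype_preset()]
#' @param channels channel ids to synthesize (default: all 32); restricting
#'   the set speeds up small studies
#' @return list with `rec` (`eeg_recording` incl. accelerometer), `events`
#'   (ground-truth `interval_events`: per-channel spindles, recording-wide
#'   swd and artifact rows), `hypnogram`, `params`, `preset`
#' @export
synth_recording <- function(hyp, array, params = sim_params(),
                            preset = genotype_preset("control"),
                            channels = NULL) {
  if (is.list(hyp) && !inherits(hyp, "hypnogram")) hyp <- hyp$hypnogram
  stopifnot(inherits(hyp, "hypnogram"), inherits(array, "electrode_array"))
  fs <- params$fs
  spe <- round(hyp$epoch_s * fs)
  if (abs(spe - hyp$epoch_s * fs) > 1e-9) stop("sample-rate/epoch mismatch")
  n_ep <- length(hyp$labels)
  n <- n_ep * spe
  channels <- sort(as.integer(channels %||% array$id))
  nc <- length(channels)
  col_of <- stats::setNames(seq_len(nc), channels)
  grp <- region_group(array)
  names(grp) <- array$id
  dmat <- pairwise_distances(array)

  state_per_sample <- rep(hyp$labels, each = spe)
  sc <- function(values) unname(values[state_per_sample])   # per-sample scale

  with_seed(derive_seed(params$seed, 2), {
    X <- matrix(0, nrow = n, ncol = nc)

    ## 1/f background, state-scaled
    for (j in seq_len(nc))
      X[, j] <- pink_noise(n, fs, params$bg_exponent) * sc(params$bg_rms_uV)

    ## independent per-channel state oscillators
    for (st in names(params$osc)) {
      o <- params$osc[[st]]
      gate <- state_per_sample == st
      if (!any(gate)) next
      for (j in seq_len(nc))
        X[gate, j] <- X[gate, j] + band_noise(n, fs, o$freq)[gate] * o$rms
    }

    ## per-region shared sources with per-channel lags
    for (cp in params$coupling) {
      gate <- state_per_sample == cp$state
      if (!any(gate) || cp$gain == 0 || cp$rms == 0) next
      atten <- if (identical(cp$state, "NREM") && cp$band[1] >= 12)
        preset$coupling_atten else 1
      for (g in unique(grp[as.character(channels)])) {
        members <- channels[grp[as.character(channels)] == g]
        if (!length(members)) next
        src <- band_noise(n, fs, cp$band) * cp$rms
        for (k in seq_along(members)) {
          lag <- round((k - 1) * cp$lag_step_ms / 1000 * fs)
          j <- col_of[[as.character(members[k])]]
          X[gate, j] <- X[gate, j] +
            cp$gain * atten * lag_shift(src, lag)[gate]
        }
      }
    }

    events <- list()

    ## planted spindles during NREM bouts
    rl <- rle(hyp$labels)
    b_end <- cumsum(rl$lengths); b_start <- b_end - rl$lengths + 1
    spd <- params$spindle
    if (spd$rate_per_min > 0) {
      for (bi in which(rl$values == "NREM")) {
        bout_s <- (b_start[bi] - 1) * hyp$epoch_s
        bout_e <- b_end[bi] * hyp$epoch_s
        n_spin <- stats::rpois(1, spd$rate_per_min * (bout_e - bout_s) / 60)
        if (n_spin == 0) next
        for (sp in seq_len(n_spin)) {
          dur <- stats::runif(1, spd$dur_range_s[1], spd$dur_range_s[2])
          if (bout_e - bout_s < dur + 0.4) next
          t0 <- stats::runif(1, bout_s + 0.2, bout_e - dur - 0.2)
          f0 <- stats::runif(1, spd$freq_range_hz[1], spd$freq_range_hz[2])
          seed_ch <- sample(channels, 1)
          near <- channels[dmat[as.character(seed_ch), as.character(channels)] <= 2]
          m <- round(dur * fs)
          tt <- (0:(m - 1)) / fs
          burst <- spd$amp_uV * 0.5 * (1 - cos(2 * pi * (0:(m - 1)) / (m - 1))) *
            sin(2 * pi * f0 * tt)
          for (ch in near) {
            gain <- if (ch == seed_ch) 1 else spd$group_gain * preset$coupling_atten
            lag <- if (ch == seed_ch) 0 else
              round(match(ch, near) * spd$lag_step_ms / 1000 * fs)
            i0 <- round(t0 * fs) + 1 + lag
            if (i0 + m - 1 > n) next
            j <- col_of[[as.character(ch)]]
            X[i0:(i0 + m - 1), j] <- X[i0:(i0 + m - 1), j] + gain * burst
            events[[length(events) + 1]] <- interval_events(
              kind = "spindle", channel = ch, start_s = (i0 - 1) / fs,
              end_s = (i0 - 1) / fs + dur, freq_hz = f0,
              amp_uV = spd$amp_uV * gain, seed_channel = seed_ch)
          }
        }
      }
    }

    ## spike-and-wave discharges during wake (generalized across channels)
    swd <- params$swd
    swd_rate <- swd$rate_per_min * preset$swd_rate_mult
    if (swd_rate > 0) {
      for (bi in which(rl$values == "WAKE")) {
        bout_s <- (b_start[bi] - 1) * hyp$epoch_s
        bout_e <- b_end[bi] * hyp$epoch_s
        n_ev <- stats::rpois(1, swd_rate * (bout_e - bout_s) / 60)
        if (n_ev == 0) next
        placed <- matrix(numeric(0), ncol = 2)
        for (ev in seq_len(n_ev)) {
          dur <- stats::runif(1, swd$dur_range_s[1], swd$dur_range_s[2])
          if (bout_e - bout_s < dur + 0.4) next
          ## discharges do not superpose: rejection-sample the onset
          t0 <- NA
          for (try in 1:20) {
            cand <- stats::runif(1, bout_s + 0.2, bout_e - dur - 0.2)
            if (!nrow(placed) ||
                !any(intervals_overlap(placed[, 1] - 0.5, placed[, 2] + 0.5,
                                       cand, cand + dur))) { t0 <- cand; break }
          }
          if (is.na(t0)) next
          placed <- rbind(placed, c(t0, t0 + dur))
          f0 <- stats::runif(1, swd$fund_range_hz[1], swd$fund_range_hz[2])
          m <- round(dur * fs)
          tt <- (0:(m - 1)) / fs
          wave <- numeric(m)
          for (k in seq_len(swd$n_harmonics + 1))
            wave <- wave + 0.5^(k - 1) * sin(2 * pi * k * f0 * tt +
                                             stats::runif(1, 0, 2 * pi))
          wave <- swd$amp_uV * wave / max(abs(wave)) *
            ifelse(tt < 0.05, tt / 0.05, ifelse(tt > dur - 0.05,
                                                (dur - tt) / 0.05, 1))
          i0 <- round(t0 * fs) + 1
          gains <- stats::runif(nc, 0.7, 1)
          for (j in seq_len(nc))
            X[i0:(i0 + m - 1), j] <- X[i0:(i0 + m - 1), j] + gains[j] * wave
          events[[length(events) + 1]] <- interval_events(
            kind = "swd", channel = NA_integer_, start_s = t0,
            end_s = t0 + dur, freq_hz = f0, amp_uV = swd$amp_uV,
            seed_channel = NA_integer_)
        }
      }
    }

    ## biphasic movement artifacts during wake
    art <- params$artifact
    accel_burst <- numeric(n)
    if (art$rate_per_min > 0) {
      wake_s <- sum(rl$lengths[rl$values == "WAKE"]) * hyp$epoch_s
      n_art <- stats::rpois(1, art$rate_per_min * wake_s / 60)
      wake_epochs <- which(hyp$labels == "WAKE")
      swd_iv <- do.call(rbind, lapply(events, function(e)
        if (e$kind[1] == "swd") c(e$start_s, e$end_s)))
      if (n_art > 0 && length(wake_epochs) > 0) {
        for (k in seq_len(n_art)) {
          t0 <- NA
          for (try in 1:20) {
            ep <- sample(wake_epochs, 1)
            cand <- (ep - 1) * hyp$epoch_s +
              stats::runif(1, 0.1, hyp$epoch_s - art$dur_s - 0.1)
            if (is.null(swd_iv) ||
                !any(intervals_overlap(swd_iv[, 1], swd_iv[, 2],
                                       cand, cand + art$dur_s))) {
              t0 <- cand; break
            }
          }
          if (is.na(t0)) next
          m <- round(art$dur_s * fs)
          pulse <- art$amp_uV * sin(2 * pi * (0:(m - 1)) / m) *
            exp(-((0:(m - 1)) - m / 2)^2 / (m / 3)^2)
          pk <- max(abs(pulse))
          pulse <- pulse * art$amp_uV / pk
          i0 <- round(t0 * fs) + 1
          for (j in seq_len(nc))
            X[i0:(i0 + m - 1), j] <- X[i0:(i0 + m - 1), j] + pulse
          accel_burst[i0:(i0 + m - 1)] <- 2
          events[[length(events) + 1]] <- interval_events(
            kind = "artifact", channel = NA_integer_, start_s = t0,
            end_s = t0 + art$dur_s, freq_hz = NA_real_,
            amp_uV = art$amp_uV, seed_channel = NA_integer_)
        }
      }
    }

    accel <- stats::rnorm(n) * sc(params$accel_sd) + accel_burst

    rec <- eeg_recording(X, fs, channel_ids = channels,
                         labels = array$label[match(channels, array$id)],
                         accel = accel)
    list(rec = rec, events = do.call(bind_events, events), hypnogram = hyp,
         params = params, preset = preset)
  })
}

#' Write / read simulation parameters as YAML (provenance)
#'
#' @param params a [sim_params()] list
#' @param path YAML file path
#' @return `path` / a `sim_params` list
#' @export
write_sim_params <- function(params, path) {
  p <- unclass(params)
  for (nm in c("dwell_mean_s", "bg_rms_uV", "accel_sd"))
    p[[nm]] <- as.list(p[[nm]])       # keep names through the YAML map
  yaml::write_yaml(p, path)
  invisible(path)
}

#' @rdname write_sim_params
#' @export
read_sim_params <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$dwell_mean_s <- unlist(raw$dwell_mean_s)
  raw$bg_rms_uV <- unlist(raw$bg_rms_uV)
  raw$accel_sd <- unlist(raw$accel_sd)
  do.call(sim_params, raw)
}
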