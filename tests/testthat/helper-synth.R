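## shared fixtures and scoring helpers for the suite

the_array <- default_electrode_array()

## overlap-based recall/precision of detected vs ground-truth intervals
match_score <- function(gt, det) {
  hit <- function(a, b) if (!nrow(a)) NA_real_ else
    mean(vapply(seq_len(nrow(a)), function(i)
      any(b$start_s < a$end_s[i] & b$end_s > a$start_s[i]), TRUE))
  list(recall = hit(gt, det), precision = hit(det, gt),
       n_gt = nrow(gt), n_det = nrow(det))
}

## a small NREM-rich simulated animal for detector tests
sim_nrem_animal <- function(seed, duration_s = 900, fs = 250,
                            channels = c(14, 15, 18, 19),
                            preset = genotype_preset("control")) {
  p <- sim_params(fs = fs, duration_s = duration_s, seed = seed,
                  dwell_mean_s = c(WAKE = 80, NREM = 150, REM = 60))
  ss <- sample_state_sequence(p, preset)
  sim <- synth_recording(ss$hypnogram, the_array, p, preset,
                         channels = channels)
  sim$bouts <- ss$bouts
  sim
}

## a wake-rich mutant animal (frequent discharges) for SWD tests
sim_wake_animal <- function(seed, duration_s = 900, fs = 250) {
  preset <- genotype_preset("mutant")
  p <- sim_params(fs = fs, duration_s = duration_s, seed = seed,
                  dwell_mean_s = c(WAKE = 200, NREM = 80, REM = 40))
  ss <- sample_state_sequence(p, preset)
  synth_recording(ss$hypnogram, the_array, p, preset, channels = 18)
}

## Hann-enveloped sinusoidal burst, peak amplitude `amp`
hann_burst <- function(dur_s, f0, fs, amp) {
  m <- round(dur_s * fs)
  amp * 0.5 * (1 - cos(2 * pi * (0:(m - 1)) / (m - 1))) *
    sin(2 * pi * f0 * (0:(m - 1)) / fs)
}

## place a waveform into a zero/noise trace at t0 seconds
plant <- function(x, wave, t0, fs) {
  i0 <- round(t0 * fs) + 1
  x[i0:(i0 + length(wave) - 1)] <- x[i0:(i0 + length(wave) - 1)] + wave
  x
}

## harmonic spike-and-wave train with square envelope
swd_train <- function(dur_s, f0, fs, amp, n_harm = 3) {
  tt <- (0:(round(dur_s * fs) - 1)) / fs
  w <- numeric(length(tt))
  for (k in seq_len(n_harm + 1)) w <- w + 0.5^(k - 1) * sin(2 * pi * k * f0 * tt)
  amp * w / max(abs(w))
}
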