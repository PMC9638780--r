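test_that("Morlet coefficients localize frequency and time", {
  fs <- 1000
  t <- (0:(4 * fs - 1)) / fs
  tf <- morlet_tfr(sin(2 * pi * 14 * t), fs, 1.0)
  expect_equal(dim(tf), c(1, 11, 2000))
  expect_equal(attr(tf, "freqs"), seq(12, 17, 0.5))
  prof <- apply(abs(tf[1, , ]), 1, mean)
  expect_equal(attr(tf, "freqs")[which.max(prof)], 14)
  ## constant amplitude over time at the matched component
  a14 <- abs(tf[1, 5, ])
  expect_lt(sd(a14) / mean(a14), 0.01)

  expect_true(all(abs(morlet_tfr(numeric(4 * fs), fs, 1.0)) == 0))

  ## impulse energy confined to the wavelet support (3 SD at 12 Hz ~ 279 ms)
  x <- numeric(4 * fs); x[2 * fs] <- 1
  tfi <- morlet_tfr(x, fs, 1.5)            # impulse at +500 ms in the window
  a <- abs(tfi[1, 1, ])
  times <- attr(tfi, "times")
  expect_lt(max(a[abs(times - 0.5) > 0.30]), max(a) * 1e-6)

  ## events too close to the record edge are dropped and reported
  tf2 <- morlet_tfr(sin(2 * pi * 14 * t), fs, c(0.05, 1.0))
  expect_equal(dim(tf2)[1], 1)
  expect_equal(attr(tf2, "dropped"), 1L)
  expect_error(morlet_tfr(sin(2 * pi * 14 * t), fs, 0.05), "no event window")
})

test_that("event coherograms follow the trial-sum formula", {
  fs <- 1000
  t <- (0:(4 * fs - 1)) / fs
  set.seed(7)
  tf <- morlet_tfr(sin(2 * pi * 14 * t) + rnorm(4 * fs) * 0.1, fs,
                   c(0.8, 1.0, 1.2))
  ## self-coherency is real
  cg0 <- event_coherogram(tf, tf)
  expect_lt(max(abs(cg0$values)), 1e-12)

  ## constant 90 deg phase shift: |value| = 1 wherever amplitude is nonzero
  tfy <- tf * exp(-1i * pi / 2)
  cg <- event_coherogram(tf, tfy)
  expect_equal(dim(cg$values), c(11, 2000))
  expect_equal(max(abs(cg$values)), 1, tolerance = 1e-9)
  expect_gt(mean(abs(cg$values) > 0.99), 0.95)

  ## direct evaluation on constructed coefficients
  ntr <- 4
  W <- array(complex(modulus = runif(ntr * 11 * 50, 0.5, 1),
                     argument = runif(ntr * 11 * 50, 0, 2 * pi)),
             dim = c(ntr, 11, 50))
  V <- array(complex(modulus = runif(ntr * 11 * 50, 0.5, 1),
                     argument = runif(ntr * 11 * 50, 0, 2 * pi)),
             dim = c(ntr, 11, 50))
  attr(W, "freqs") <- attr(V, "freqs") <- seq(12, 17, 0.5)
  attr(W, "times") <- attr(V, "times") <- seq_len(50)
  cg2 <- event_coherogram(W, V)
  i <- 6; j <- 17
  direct <- Im(sum(W[, i, j] * Conj(V[, i, j])) /
               sqrt(sum(Mod(W[, i, j])^2) * sum(Mod(V[, i, j])^2)))
  expect_equal(cg2$values[i, j], direct, tolerance = 1e-12)

  ## independent random phases: coherence shrinks like 1/sqrt(n_trials)
  expect_lt(mean(abs(cg2$values)), 2 / sqrt(ntr))
})

test_that("high-connectivity counting is exact and scale invariant", {
  freqs <- seq(12, 17, 0.5)
  mk <- function(v) structure(list(freq = freqs, times = seq_len(ncol(v)),
                                   values = v, n_trials = 5),
                              class = "coherogram")
  v <- matrix(0.1, 11, 40)
  v[5, 10] <- 0.5
  hc <- high_connectivity(mk(v), 0.70)
  expect_equal(hc$n_supra_bins, 1L)
  expect_equal(hc$mean_freq_hz, 14)

  u <- matrix(0.3, 11, 40)
  expect_equal(high_connectivity(mk(u), 0.70)$n_supra_bins, 11L * 40L)

  set.seed(11)
  r <- matrix(runif(11 * 2000, -1, 1), 11, 2000)
  hc2 <- high_connectivity(mk(r), 0.70)
  ## exhaustive scan oracle
  M <- 0
  for (i in 1:11) for (j in 1:2000) M <- max(M, abs(r[i, j]))
  cnt <- 0L; fsum <- 0
  for (i in 1:11) for (j in 1:2000)
    if (abs(r[i, j]) > 0.70 * M) { cnt <- cnt + 1L; fsum <- fsum + freqs[i] }
  expect_equal(hc2$n_supra_bins, cnt)
  expect_equal(hc2$mean_freq_hz, fsum / cnt)
  ## threshold is relative: scaling changes nothing
  hc3 <- high_connectivity(mk(0.37 * r), 0.70)
  expect_equal(hc3$n_supra_bins, hc2$n_supra_bins)

  z <- high_connectivity(mk(matrix(0, 11, 5)), 0.70)
  expect_equal(z$n_supra_bins, 0L)
  expect_true(is.na(z$mean_freq_hz))
})

test_that("spindle-locked coherograms reflect planted lagged bursts", {
  p <- sim_params(fs = 1000, duration_s = 120, seed = 71,
                  spindle = list(rate_per_min = 5, dur_range_s = c(0.6, 1.0),
                                 freq_range_hz = c(14, 14), amp_uV = 100,
                                 group_gain = 0.8, lag_step_ms = 2))
  h <- hypnogram(rep("NREM", 24))
  sim <- synth_recording(h, the_array, p, channels = c(14, 15, 18, 19))
  gt <- sim$events[sim$events$kind == "spindle" & sim$events$channel == 18, ]
  expect_gte(nrow(gt), 2)
  sel <- data.frame(chan_a = c(14, 18), chan_b = c(15, 19))
  cg <- spindle_coherogram(sim$rec, gt$start_s, sel)
  expect_equal(dim(cg$values), c(11, 2000))
  ## connectivity concentrates during the burst window, not before it
  during <- cg$times > 0.05 & cg$times < 0.55
  before <- cg$times < -0.1
  expect_gt(mean(abs(cg$values[, during])), mean(abs(cg$values[, before])))
})
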