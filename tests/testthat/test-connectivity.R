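test_that("decimation preserves passband and rejects aliasing", {
  fs <- 1000; n <- fs * 20
  t <- (0:(n - 1)) / fs
  rec <- eeg_recording(cbind(sin(2 * pi * 4 * t)), fs)
  d <- decimate8(rec)
  expect_equal(d$fs, 125)
  expect_equal(nrow(d$data), n / 8)
  td <- (0:(nrow(d$data) - 1)) / 125
  fit <- lm(d$data[, 1] ~ sin(2 * pi * 4 * td) + cos(2 * pi * 4 * td))
  expect_lt(abs(sqrt(sum(coef(fit)[2:3]^2)) - 1), 0.05)

  rec70 <- eeg_recording(cbind(sin(2 * pi * 70 * t)), fs)
  expect_lt(sd(decimate8(rec70)$data[, 1]) / sd(rec70$data[, 1]), 0.05)

  expect_error(decimate_recording(eeg_recording(cbind(rnorm(500)), 100), 8),
               "not divisible")
})

test_that("imaginary coherency vanishes for identical and zero-lag mixed signals", {
  set.seed(4)
  fs <- 125; n <- fs * 120
  x <- rnorm(n)
  expect_lt(max(abs(imaginary_coherency(x, x, fs))), 1e-10)
  z <- rnorm(n)
  y <- 2 * x + 0.7 * z                      # zero-phase mixture
  expect_lt(mean(abs(imaginary_coherency(x, y, fs))), 0.03)
})

test_that("a pure lag produces signed imaginary coherence matching a DFT oracle", {
  set.seed(5)
  fs <- 125; n <- fs * 400
  t <- (0:(n - 1)) / fs
  s <- sin(2 * pi * 10 * t)
  lag <- round(0.025 * fs)                  # 25 ms = 90 deg at 10 Hz
  x <- s + rnorm(n) * 0.5
  y <- c(numeric(lag), s)[1:n] + rnorm(n) * 0.5
  v <- imaginary_coherency(x, y, fs)
  v10 <- v[attr(v, "freq") == 10]
  expect_gte(abs(v10), 0.8)

  ## independent oracle: single long-segment DFT cross-spectrum at 10 Hz,
  ## averaged over disjoint 4 s blocks
  blocks <- split(seq_len(n), rep(seq_len(n / (4 * fs)), each = 4 * fs))
  sxy <- sxx <- syy <- 0
  for (b in blocks) {
    k <- 10 * 4 + 1                         # 10 Hz bin of a 4 s block
    X <- fft(x[b])[k]; Y <- fft(y[b])[k]
    sxy <- sxy + X * Conj(Y); sxx <- sxx + Mod(X)^2; syy <- syy + Mod(Y)^2
  }
  oracle <- Im(sxy / sqrt(sxx * syy))
  expect_equal(sign(v10), sign(oracle))
  expect_lt(abs(v10 - oracle), 0.1)

  ## swapping the pair negates every bin
  expect_equal(imaginary_coherency(y, x, fs), -v,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("Fisher averaging is exact on closed-form cases", {
  expect_equal(fisher_mean(rep(0.37, 6)), 0.37, tolerance = 1e-12)
  expect_equal(fisher_mean(c(0.4, -0.4)), 0, tolerance = 1e-12)
  expect_equal(fisher_mean(c(0.2, 0.6)),
               tanh((atanh(0.2) + atanh(0.6)) / 2), tolerance = 1e-14)
  expect_warning(v <- fisher_mean(c(0.5, 1)), "clipped")
  expect_lt(v, 1)
  ## round-trip identity across magnitudes
  for (r in c(-0.99, -0.5, 0, 0.5, 0.99))
    expect_equal(fisher_mean(rep(r, 3)), r, tolerance = 1e-12)
})

test_that("state spectra elevate only where lagged coupling is planted", {
  p <- sim_params(fs = 1000, duration_s = 100, seed = 61)
  h <- hypnogram(rep("NREM", 20))
  sim <- synth_recording(h, the_array, p, channels = c(14, 15, 18, 19))
  dec <- decimate8(sim$rec)
  cp <- state_pair_spectrum(dec, h, "NREM", c(18, 19))     # same region group
  expect_s3_class(cp, "coherence_pair")
  expect_length(cp$z_inv_values, 99)
  expect_true(all(abs(cp$z_inv_values) < 1, na.rm = TRUE))
  sigma <- cp$freq >= 12 & cp$freq <= 17
  expect_gt(mean(abs(cp$z_inv_values[sigma])),
            mean(abs(cp$z_inv_values[cp$freq >= 30])) + 0.05)

  ## wake epochs carry no NREM-state coupling
  h2 <- hypnogram(rep("WAKE", 20))
  sim2 <- synth_recording(h2, the_array, p, channels = c(18, 19))
  cp2 <- state_pair_spectrum(decimate8(sim2$rec), h2, "WAKE", c(18, 19))
  expect_lt(mean(abs(cp2$z_inv_values[sigma])), 0.1)

  ## single epoch equals that epoch's raw values
  h1 <- hypnogram(c("NREM", rep("EXCLUDED", 19)))
  cp1 <- state_pair_spectrum(dec, h1, "NREM", c(18, 19))
  raw <- imaginary_coherency(dec$data[1:625, 3], dec$data[1:625, 4], 125)
  expect_equal(cp1$z_inv_values, as.numeric(raw), tolerance = 1e-9)
})

test_that("the all-pairs path agrees with the per-pair path", {
  p <- sim_params(fs = 1000, duration_s = 50, seed = 62)
  h <- hypnogram(rep("NREM", 10))
  sim <- synth_recording(h, the_array, p, channels = c(14, 15, 18))
  dec <- decimate8(sim$rec)
  all <- state_coherence_all(dec, h, "NREM")
  for (pr in list(c(14, 15), c(14, 18), c(15, 18))) {
    one <- state_pair_spectrum(dec, h, "NREM", pr)
    key <- paste0(pr[1], "-", pr[2])
    expect_equal(all[[key]]$z_inv_values, one$z_inv_values, tolerance = 1e-9)
  }
})

test_that("group averaging and regional mode behave as specified", {
  mk <- function(pair, val) structure(
    list(pair = pair, freq = COH_GRID, z_inv_values = rep(val, 99),
         n_epochs = 5), class = "coherence_pair")
  pairs <- list("1-2" = mk(c(1, 2), 0.1), "3-4" = mk(c(3, 4), 0.3))
  sel <- data.frame(chan_a = c(1, 3), chan_b = c(2, 4))
  gs <- group_average(pairs, sel)
  expect_equal(gs$values, rep(0.2, 99))
  expect_error(group_average(pairs, sel[0, ]), "empty selection")

  ## region mode with identical member sets gives zero coherency
  p <- sim_params(fs = 1000, duration_s = 50, seed = 63)
  h <- hypnogram(rep("NREM", 10))
  sim <- synth_recording(h, the_array, p, channels = c(14, 15, 18, 19))
  dec <- decimate8(sim$rec)
  tab <- as.data.frame(the_array)
  arr <- electrode_array(tab)
  rs <- region_pair_spectrum(dec, h, "NREM", arr, "right middle", "right middle")
  expect_lt(max(abs(rs$z_inv_values)), 1e-10)
})

test_that("zero-lag mixing across a whole group stays below the volume-conduction bound", {
  set.seed(64)
  fs <- 125; n_ep <- 30; n <- n_ep * 5 * fs
  src <- matrix(rnorm(n * 3), ncol = 3)
  mix <- matrix(runif(12, 0.2, 1), nrow = 3)        # instantaneous mixing
  X <- src %*% mix
  rec <- eeg_recording(X, fs, channel_ids = 0:3)
  h <- hypnogram(rep("NREM", n_ep))
  pairs <- state_coherence_all(rec, h, "NREM")
  sel <- data.frame(chan_a = c(0, 0, 0, 1, 1, 2), chan_b = c(1, 2, 3, 2, 3, 3))
  gs <- group_average(pairs, sel)
  expect_lt(max(abs(gs$values)), 0.05)
})
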