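nrem_bg <- function(seed, dur_s, fs) {
  ## NREM-like background: 1/f^2 noise + delta, modest sigma-band content
  set.seed(seed)
  n <- dur_s * fs
  f <- (1:(n %/% 2)) * fs / n
  amp <- f^-1
  spec <- complex(modulus = amp, argument = runif(n %/% 2, 0, 2 * pi))
  full <- c(0, spec, Conj(rev(spec[-(n %/% 2)])))
  bg <- Re(fft(full, inverse = TRUE) / n)
  15 * bg / sd(bg)   # quiet background: crossings stay below the 25 uV floor
}

test_that("a planted burst is recovered with its duration and frequency", {
  fs <- 250; dur <- 120
  x <- nrem_bg(1, dur, fs)
  x <- plant(x, hann_burst(0.6, 14, fs, 100), 33.2, fs)
  ev <- detect_spindles(x, fs, rep(TRUE, dur / 5))
  hit <- ev[ev$start_s < 33.8 & ev$end_s > 33.2, ]
  expect_equal(nrow(hit), 1)
  expect_lte(abs(hit$duration_s - 0.6), 0.1)
  expect_lte(abs(hit$peak_freq_hz - 14), 0.5)
})

test_that("duration window, merge gap and amplitude window behave exactly", {
  fs <- 250; dur <- 120
  base <- nrem_bg(2, dur, fs)
  mask <- rep(TRUE, dur / 5)
  near <- function(ev, t0) ev[ev$start_s < t0 + 1 & ev$end_s > t0 - 1, ]

  ## the duration window acts on the measured burst core
  x <- plant(base, hann_burst(0.5, 14, fs, 120), 50, fs)
  expect_equal(nrow(near(detect_spindles(x, fs, mask), 50)), 1)
  expect_equal(nrow(near(detect_spindles(x, fs, mask,
                           spindle_params(min_dur_s = 0.8)), 50)), 0)
  expect_equal(nrow(near(detect_spindles(x, fs, mask,
                           spindle_params(max_dur_s = 0.3)), 50)), 0)

  ## a burst whose measured core exceeds the 3 s maximum is dropped
  x <- plant(base, hann_burst(6, 14, fs, 120), 50, fs)
  expect_equal(nrow(near(detect_spindles(x, fs, mask), 52)), 0)

  ## two bursts 0.1 s apart (< 0.2 s gap) merge; 0.5 s apart they stay separate
  x <- plant(base, hann_burst(0.5, 14, fs, 120), 50, fs)
  x <- plant(x, hann_burst(0.5, 14, fs, 120), 50.6, fs)
  ev <- near(detect_spindles(x, fs, mask), 50.5)
  expect_equal(nrow(ev), 1)
  expect_gt(ev$duration_s, 0.9)
  x <- plant(base, hann_burst(0.5, 14, fs, 120), 50, fs)
  x <- plant(x, hann_burst(0.5, 14, fs, 120), 51.0, fs)
  expect_equal(nrow(near(detect_spindles(x, fs, mask), 50.7)), 2)

  ## peak-to-trough above 750 uV is rejected; below 25 uV is never kept
  x <- plant(base, hann_burst(0.6, 14, fs, 500), 50, fs)   # p2t ~ 1000
  expect_equal(nrow(near(detect_spindles(x, fs, mask), 50)), 0)
  x <- plant(base, hann_burst(0.6, 14, fs, 8), 50, fs)     # p2t ~ 16
  expect_equal(nrow(near(detect_spindles(x, fs, mask), 50)), 0)
})

test_that("a sub-minimum burst at plausible amplitude yields no event", {
  sim <- sim_nrem_animal(seed = 77, duration_s = 900, channels = 18)
  mask <- sim$hypnogram$labels == "NREM"
  x <- channel_signal(sim$rec, 18)
  ## a clear NREM moment away from any planted spindle
  r <- rle(sim$hypnogram$labels)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  long <- which(r$values == "NREM" & r$lengths >= 8)
  gt <- sim$events[sim$events$kind == "spindle", ]
  t0 <- NA
  for (k in long) for (cand in seq((starts[k] + 1) * 5, (ends[k] - 2) * 5, 5))
    if (is.na(t0) && all(abs(gt$start_s - cand) > 4)) t0 <- cand
  x <- plant(x, hann_burst(0.1, 14, 250, 60), t0, 250)
  ev <- detect_spindles(x, 250, mask)
  expect_equal(nrow(ev[ev$start_s < t0 + 1 & ev$end_s > t0 - 1, ]), 0)
})

test_that("all detected spindles lie within NREM-masked time", {
  sim <- sim_nrem_animal(seed = 41, duration_s = 600)
  mask <- sim$hypnogram$labels == "NREM"
  ev <- detect_spindles(channel_signal(sim$rec, 18), 250, mask, channel = 18)
  expect_gt(nrow(ev), 0)
  for (i in seq_len(nrow(ev))) {
    epochs <- unique(floor(c(ev$start_s[i], ev$end_s[i] - 1e-9) / 5)) + 1
    expect_true(all(mask[epochs]))
  }
  expect_error(detect_spindles(channel_signal(sim$rec, 18), 250,
                               rep(FALSE, length(mask))), "empty NREM")
})

test_that("spindle recovery on synthetic ground truth is accurate", {
  sim <- sim_nrem_animal(seed = 52, duration_s = 900)
  mask <- sim$hypnogram$labels == "NREM"
  ev <- detect_spindles(channel_signal(sim$rec, 18), 250, mask, channel = 18)
  gt <- sim$events[sim$events$kind == "spindle" & sim$events$channel == 18, ]
  sc <- match_score(gt, ev)
  expect_gte(sc$recall, 0.9)
  expect_gte(sc$precision, 0.9)
})

test_that("multi-electrode grouping follows distance and overlap rules", {
  ## identical spindle on three mutually-near channels: one group of 3
  ev <- interval_events(kind = "spindle", channel = c(14L, 15L, 18L),
                        start_s = rep(10, 3), end_s = rep(10.8, 3))
  g <- multisite_spindles(ev, the_array, radius_mm = 2)
  expect_equal(g$n_multielectrode, 1)
  expect_equal(g$mean_electrodes, 3)

  ## two channels ~5 mm apart: no group
  ev2 <- interval_events(kind = "spindle", channel = c(0L, 19L),
                         start_s = c(5, 5), end_s = c(5.5, 5.5))
  expect_equal(multisite_spindles(ev2, the_array)$n_multielectrode, 0)

  expect_error(multisite_spindles(
    interval_events(kind = "spindle", channel = 99L, start_s = 1, end_s = 2),
    the_array), "unknown channel")
})

test_that("grouping matches a graph connected-components oracle", {
  skip_if_not_installed("igraph")
  set.seed(9)
  n <- 60
  starts <- round(runif(n, 0, 50), 2)
  ev <- interval_events(kind = "spindle",
                        channel = sample(the_array$id, n, replace = TRUE),
                        start_s = starts,
                        end_s = starts + runif(n, 0.3, 1.2))
  ev <- ev[!duplicated(paste(ev$channel, round(ev$start_s, 1))), ]
  n <- nrow(ev)
  g <- multisite_spindles(ev, the_array, radius_mm = 2)
  d <- pairwise_distances(the_array)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    adj[i, j] <- ev$channel[i] != ev$channel[j] &&
      d[as.character(ev$channel[i]), as.character(ev$channel[j])] <= 2 &&
      ev$start_s[i] < ev$end_s[j] && ev$start_s[j] < ev$end_s[i]
  }
  gr <- igraph::graph_from_adjacency_matrix(adj | t(adj), mode = "undirected")
  comp <- igraph::components(gr)
  sizes <- tapply(ev$channel, comp$membership, function(ch) length(unique(ch)))
  expect_equal(g$n_multielectrode, sum(sizes >= 2))
  if (g$n_multielectrode > 0)
    expect_equal(g$mean_electrodes, mean(sizes[sizes >= 2]))
})
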