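test_that("bout statistics match hand-counted examples", {
  b <- bout_statistics(hypnogram(c("WAKE", "WAKE", "NREM", "NREM", "NREM", "REM")))
  expect_equal(b$n_bouts, c(1, 1, 1))
  expect_equal(b$mean_bout_s, c(10, 15, 5))
  expect_equal(b$percent_time, c(100 / 3, 50, 100 / 6))

  b2 <- bout_statistics(hypnogram(c("WAKE", "EXCLUDED", "WAKE")))
  expect_equal(b2$n_bouts[b2$state == "WAKE"], 2)
  expect_equal(b2$mean_bout_s[b2$state == "WAKE"], 5)
  expect_equal(b2$percent_time[b2$state == "WAKE"], 100)

  b3 <- bout_statistics(hypnogram(rep("EXCLUDED", 4)))
  expect_true(all(is.na(b3$percent_time)))
  expect_true(isTRUE(attr(b3, "all_excluded")))
})

test_that("bout counts agree with an independent run-length oracle", {
  set.seed(42)
  labels <- sample(c("WAKE", "NREM", "REM", "EXCLUDED"), 1000, replace = TRUE)
  b <- bout_statistics(hypnogram(labels))
  ## brute-force scan oracle
  oracle <- c(WAKE = 0L, NREM = 0L, REM = 0L)
  prev <- "EXCLUDED"
  for (l in labels) {
    if (l != "EXCLUDED" && l != prev) oracle[l] <- oracle[l] + 1L
    prev <- l
  }
  expect_equal(setNames(b$n_bouts, b$state), oracle)
  ## time conservation
  expect_equal(sum(b$total_s), 5 * sum(labels != "EXCLUDED"))
  expect_equal(sum(b$percent_time), 100)
})

test_that("bout statistics ignore padding with EXCLUDED epochs", {
  set.seed(7)
  labels <- sample(c("WAKE", "NREM", "REM"), 200, replace = TRUE)
  b1 <- bout_statistics(hypnogram(labels))
  b2 <- bout_statistics(hypnogram(c(rep("EXCLUDED", 5), labels,
                                    rep("EXCLUDED", 3))))
  expect_equal(b1, b2)
})

test_that("event-time exclusion marks exactly the overlapping epochs", {
  h <- hypnogram(rep("WAKE", 4))
  ev <- interval_events(kind = "swd", channel = NA, start_s = 6, end_s = 8)
  h2 <- exclude_event_times(h, ev)
  expect_equal(h2$labels, c("WAKE", "EXCLUDED", "WAKE", "WAKE"))
  expect_equal(exclude_event_times(h, empty_events())$labels, h$labels)
  expect_equal(exclude_event_times(h2, ev)$labels, h2$labels)   # idempotent
  full <- interval_events(kind = "swd", channel = NA, start_s = 0, end_s = 20)
  expect_true(all(exclude_event_times(h, full)$labels == "EXCLUDED"))
  bad <- data.frame(start_s = 5, end_s = 3)
  expect_error(exclude_event_times(h, bad), "reversed")
})

test_that("artifact masking excludes epochs with supra-threshold samples", {
  fs <- 100
  x <- matrix(0, nrow = 20 * fs, ncol = 2)
  x[12 * fs + 5, 2] <- 900
  rec <- eeg_recording(x, fs)
  h <- artifact_mask(rec, hypnogram(rep("NREM", 4)))
  expect_equal(h$labels, c("NREM", "NREM", "EXCLUDED", "NREM"))
  rec0 <- eeg_recording(matrix(0, 20 * fs, 2), fs)
  expect_true(all(artifact_mask(rec0, hypnogram(rep("NREM", 4)))$labels == "NREM"))
})

test_that("artifact masking recovers the generator's planted artifacts", {
  sim <- sim_wake_animal(seed = 31, duration_s = 600)
  h <- artifact_mask(sim$rec, sim$hypnogram)
  art <- sim$events[sim$events$kind == "artifact", ]
  truth <- rep(FALSE, length(h$labels))
  starts <- (seq_along(truth) - 1) * 5
  for (k in seq_len(nrow(art)))
    truth <- truth | (starts < art$end_s[k] & starts + 5 > art$start_s[k])
  expect_equal(h$labels == "EXCLUDED", truth)
})

test_that("rule-based scoring follows its stated rules on pure inputs", {
  fs <- 100; n <- 20 * fs
  t <- (0:(n - 1)) / fs
  delta <- 50 * sin(2 * pi * 2 * t)
  rec <- eeg_recording(cbind(delta), fs, accel = matrix(0, n, 1))
  expect_true(all(auto_score(rec, channel = 0)$labels == "NREM"))
  set.seed(5)
  rec2 <- eeg_recording(cbind(rnorm(n) * 30), fs,
                        accel = matrix(rnorm(n), n, 1))
  expect_true(all(auto_score(rec2, channel = 0)$labels == "WAKE"))
})

test_that("rule-based scoring recovers the synthetic hypnogram", {
  p <- sim_params(fs = 250, duration_s = 600, seed = 12,
                  dwell_mean_s = c(WAKE = 80, NREM = 120, REM = 60))
  ss <- sample_state_sequence(p)
  sim <- synth_recording(ss$hypnogram, the_array, p, channels = 18)
  h <- auto_score(sim$rec, channel = 18)
  expect_gte(mean(h$labels == ss$hypnogram$labels), 0.90)
})

test_that("hypnogram and event CSV round-trips preserve content", {
  h <- hypnogram(c("WAKE", "NREM", "REM", "EXCLUDED"), epoch_s = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_hypnogram(h, f)
  h2 <- read_hypnogram(f)
  expect_equal(h2$labels, h$labels)
  expect_equal(h2$epoch_s, 5)
  ev <- interval_events(kind = "spindle", channel = 3L, start_s = 1.25,
                        end_s = 2.5, amp_uV = 80)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, f2)
  expect_equal(read_events(f2)$amp_uV, 80)
})
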