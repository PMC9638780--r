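BRAIN_STATES <- c("WAKE", "NREM", "REM", "EXCLUDED")

#' Hypnogram: epoch-level brain-state labels
#'
#' @param labels character vector over WAKE/NREM/REM/EXCLUDED
#' @param epoch_s epoch length in seconds (default 5)
#' @return an object of class `hypnogram`
#' @export
hypnogram <- function(labels, epoch_s = 5) {
  labels <- as.character(labels)
  if (length(labels) < 1) stop("empty hypnogram")
  if (!all(labels %in% BRAIN_STATES))
    stop("labels must be one of ", paste(BRAIN_STATES, collapse = "/"))
  if (!is.finite(epoch_s) || epoch_s <= 0) stop("epoch_s must be positive")
  structure(list(labels = labels, epoch_s = epoch_s), class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> %d x %g s epochs: ", length(x$labels), x$epoch_s))
  print(table(factor(x$labels, BRAIN_STATES)))
  invisible(x)
}

#' Interval event table (spindles, discharges, artifacts)
#'
#' @param kind event kind: `"spindle"`, `"swd"` or `"artifact"`
#' @param channel channel id, or `NA` for recording-wide events
#' @param start_s,end_s event bounds in seconds (`end_s > start_s`)
#' @param ... further per-event property columns (recycled)
#' @return data.frame of class `interval_events`
#' @export
interval_events <- function(kind = character(), channel = NA_integer_,
                            start_s = numeric(), end_s = numeric(), ...) {
  if (length(start_s) == 0) return(empty_events())
  if (any(end_s <= start_s)) stop("negative or reversed intervals")
  df <- data.frame(kind = kind, channel = channel, start_s = start_s,
                   end_s = end_s, ...)
  class(df) <- c("interval_events", "data.frame")
  df
}

#' An empty interval-event table
#' @return an `interval_events` data.frame with zero rows
#' @export
empty_events <- function() {
  df <- data.frame(kind = character(), channel = integer(),
                   start_s = numeric(), end_s = numeric())
  class(df) <- c("interval_events", "data.frame")
  df
}

bind_events <- function(...) {
  dfs <- Filter(function(d) !is.null(d) && nrow(d) > 0, list(...))
  if (!length(dfs)) return(empty_events())
  cols <- unique(unlist(lapply(dfs, names)))
  dfs <- lapply(dfs, function(d) { d[setdiff(cols, names(d))] <- NA; d[cols] })
  out <- do.call(rbind, dfs)
  class(out) <- c("interval_events", "data.frame")
  rownames(out) <- NULL
  out
}

#' Bout statistics of a hypnogram
#'
#' A bout is a maximal run of identical non-EXCLUDED labels; EXCLUDED epochs
#' terminate bouts and are removed from the percent-time denominator.
#'
#' @param h a `hypnogram`
#' @return data.frame with one row per state (WAKE, NREM, REM) and columns
#'   `percent_time`, `n_bouts`, `mean_bout_s`, `total_s`. When every epoch is
#'   EXCLUDED, percents are `NA` and the attribute `all_excluded` is set.
#' @export
bout_statistics <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  r <- rle(h$labels)
  keep <- r$values != "EXCLUDED"
  states <- c("WAKE", "NREM", "REM")
  n_bouts <- vapply(states, function(s) sum(keep & r$values == s), 0L)
  total_s <- vapply(states, function(s)
    sum(r$lengths[keep & r$values == s]) * h$epoch_s, 0)
  denom <- sum(total_s)
  out <- data.frame(
    state = states,
    percent_time = if (denom > 0) 100 * total_s / denom else rep(NA_real_, 3),
    n_bouts = n_bouts,
    mean_bout_s = ifelse(n_bouts > 0, total_s / n_bouts, NA_real_),
    total_s = total_s, row.names = NULL)
  if (denom == 0) attr(out, "all_excluded") <- TRUE
  out
}

#' Exclude epochs overlapping event intervals
#'
#' Any epoch with positive overlap with any event interval becomes EXCLUDED.
#' Idempotent.
#'
#' @param h a `hypnogram`
#' @param events an `interval_events` table (or any data.frame with
#'   `start_s`/`end_s`)
#' @return the modified `hypnogram`
#' @export
exclude_event_times <- function(h, events) {
  stopifnot(inherits(h, "hypnogram"))
  if (is.null(events) || nrow(events) == 0) return(h)
  if (any(events$end_s <= events$start_s)) stop("negative or reversed intervals")
  n <- length(h$labels)
  starts <- (seq_len(n) - 1) * h$epoch_s
  hit <- rep(FALSE, n)
  for (k in seq_len(nrow(events)))
    hit <- hit | intervals_overlap(starts, starts + h$epoch_s,
                                   events$start_s[k], events$end_s[k])
  h$labels[hit] <- "EXCLUDED"
  h
}

#' Exclude epochs containing large-amplitude movement artifacts
#'
#' Epochs in which any analysed channel contains a sample with absolute value
#' above the threshold are marked EXCLUDED (whole-epoch exclusion).
#'
#' @param rec an `eeg_recording`
#' @param h a `hypnogram` covering the recording
#' @param threshold_uV amplitude threshold in microvolts (default 750)
#' @param channels channel ids to inspect (default: all)
#' @return the modified `hypnogram`
#' @export
artifact_mask <- function(rec, h, threshold_uV = 750, channels = NULL) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(h, "hypnogram"))
  if (threshold_uV <= 0) stop("threshold must be positive")
  cols <- if (is.null(channels)) seq_len(ncol(rec$data))
          else vapply(channels, channel_column, 0L, rec = rec)
  spe <- round(h$epoch_s * rec$fs)
  n_ep <- min(length(h$labels), nrow(rec$data) %/% spe)
  for (i in seq_len(n_ep)) {
    rows <- ((i - 1) * spe + 1):(i * spe)
    if (max(abs(rec$data[rows, cols])) > threshold_uV)
      h$labels[i] <- "EXCLUDED"
  }
  h
}

## per-epoch band power from a one-channel slice (plain periodogram)
epoch_band_powers <- function(x, fs, bands) {
  n <- length(x)
  X <- stats::fft(x - mean(x))
  p <- Mod(X[2:(floor(n / 2) + 1)])^2
  fr <- (1:floor(n / 2)) * fs / n
  vapply(bands, function(b) sum(p[fr >= b[1] & fr <= b[2]]), 0)
}

#' Rule-based automatic brain-state scoring
#'
#' A convenience surrogate for visual scoring: per 5 s epoch, quiet
#' accelerometer plus a dominant delta (1-4 Hz) fraction of 1-48 Hz power
#' yields NREM; quiet accelerometer plus a high theta (5-10 Hz) / delta ratio
#' yields REM; anything else is WAKE.
#'
#' @param rec an `eeg_recording` with an accelerometer trace (or supply `accel`)
#' @param channel EEG channel id used for spectral features
#' @param accel accelerometer trace; defaults to the recording's own
#' @param epoch_s epoch length (default 5)
#' @param delta_frac_min minimum delta fraction of 1-48 Hz power for NREM
#' @param theta_delta_min minimum theta/delta power ratio for REM
#' @param accel_sd_max accelerometer standard-deviation ceiling defining a
#'   quiet epoch, in accelerometer units
#' @return a `hypnogram`
#' @export
auto_score <- function(rec, channel, accel = NULL, epoch_s = 5,
                       delta_frac_min = 0.4, theta_delta_min = 1.5,
                       accel_sd_max = 0.3) {
  stopifnot(inherits(rec, "eeg_recording"))
  acc <- accel %||% rec$accel
  if (is.null(acc)) stop("missing accelerometer")
  acc <- as.matrix(acc)
  x <- channel_signal(rec, channel)
  spe <- round(epoch_s * rec$fs)
  n_ep <- length(x) %/% spe
  if (n_ep < 1) stop("recording shorter than one epoch")
  bands <- list(delta = c(1, 4), theta = c(5, 10), total = c(1, 48))
  labels <- character(n_ep)
  for (i in seq_len(n_ep)) {
    rows <- ((i - 1) * spe + 1):(i * spe)
    bp <- epoch_band_powers(x[rows], rec$fs, bands)
    quiet <- stats::sd(acc[rows, 1]) <= accel_sd_max
    labels[i] <-
      if (quiet && bp[1] / bp[3] > delta_frac_min) "NREM"
      else if (quiet && bp[2] / max(bp[1], .Machine$double.eps) > theta_delta_min) "REM"
      else "WAKE"
  }
  hypnogram(labels, epoch_s)
}

#' Write / read a hypnogram as CSV (`epoch_index,state`, 1-based index)
#'
#' @param h a `hypnogram`
#' @param path CSV path
#' @return `path` / a `hypnogram`
#' @export
write_hypnogram <- function(h, path) {
  writeLines(sprintf("# epoch_s=%g", h$epoch_s), path)
  suppressWarnings(utils::write.table(
    data.frame(epoch_index = seq_along(h$labels), state = h$labels),
    path, sep = ",", row.names = FALSE, append = TRUE, quote = FALSE))
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path) {
  first <- readLines(path, n = 1)
  epoch_s <- if (grepl("^# epoch_s=", first))
    as.numeric(sub("^# epoch_s=", "", first)) else 5
  df <- utils::read.csv(path, comment.char = "#")
  hypnogram(df$state[order(df$epoch_index)], epoch_s)
}

#' Write / read interval events as CSV
#'
#' @param events an `interval_events` table
#' @param path CSV path
#' @return `path` / an `interval_events` table
#' @export
write_events <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path)
  class(df) <- c("interval_events", "data.frame")
  df
}
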