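#' Multi-channel EEG recording container
#'
#' @param data numeric matrix, samples x channels, in microvolts
#' @param fs sampling rate in Hz
#' @param channel_ids integer channel ids (default `0:(ncol-1)`)
#' @param labels channel labels
#' @param accel optional accelerometer trace(s): numeric vector or matrix with
#'   the same number of samples
#' @return an object of class `eeg_recording`
#' @export
eeg_recording <- function(data, fs, channel_ids = NULL, labels = NULL,
                          accel = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data) || nrow(data) < 1) stop("data must be a numeric matrix")
  if (!is.finite(fs) || fs <= 0) stop("fs must be positive")
  channel_ids <- channel_ids %||% (seq_len(ncol(data)) - 1L)
  labels <- labels %||% paste0("ch", channel_ids)
  if (length(channel_ids) != ncol(data)) stop("channel id / column mismatch")
  if (!is.null(accel)) {
    accel <- as.matrix(accel)
    if (nrow(accel) != nrow(data)) stop("accelerometer length mismatch")
  }
  structure(list(data = data, fs = fs, channel_ids = as.integer(channel_ids),
                 labels = labels, accel = accel),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %.1f s @ %g Hz%s\n",
              ncol(x$data), nrow(x$data) / x$fs, x$fs,
              if (is.null(x$accel)) "" else sprintf(" + %d accel", ncol(x$accel))))
  invisible(x)
}

## column index of a channel id within the recording
channel_column <- function(rec, channel) {
  j <- match(channel, rec$channel_ids)
  if (is.na(j)) stop("unknown channel id: ", channel)
  j
}

#' Extract one channel's trace
#'
#' @param rec an `eeg_recording`
#' @param channel channel id
#' @return numeric vector in microvolts
#' @export
channel_signal <- function(rec, channel) rec$data[, channel_column(rec, channel)]
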