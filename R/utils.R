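#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a base seed and counters
#'
#' Expands one global seed into independent per-animal / per-stage streams via
#' a Lehmer-style counter scheme. Result is always a valid 32-bit integer.
#'
#' @param seed base integer seed
#' @param ... integer counters (e.g. animal index, stage index)
#' @return an integer seed
#' @export
derive_seed <- function(seed, ...) {
  ks <- c(...)
  s <- as.double(abs(as.integer(seed)) %% 2147483647)
  if (s == 0) s <- 1
  for (k in ks) s <- (s * 48271 + as.double(k) + 1) %% 2147483647
  as.integer(s)
}

## FNV-1a over serialized object; used to stamp outputs with a config hash
fnv1a_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (as.double(h) * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

## half-open interval overlap [s1,e1) vs [s2,e2)
intervals_overlap <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

## moving average with edge-preserving fill
moving_average <- function(x, k) {
  if (k <= 1) return(x)
  y <- stats::filter(x, rep(1 / k, k), sides = 2)
  y <- as.numeric(y)
  y[is.na(y)] <- x[is.na(y)]
  y
}

## analytic signal via frequency-domain Hilbert construction
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    if (n > 2) h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}
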