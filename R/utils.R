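# Internal numerical helpers shared across modules.

#' @importFrom stats fft rnorm runif rbinom sd qt pf pt
#' @importFrom utils read.table write.table head tail
NULL

## Classed error constructor: every domain error carries class
## c("sophase_<what>", "sophase_error", "error", "condition") so callers
## (notably the predictor state machine) can react without string matching.
so_stop <- function(what, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("sophase_", what), "sophase_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

## Wrap angles (degrees) to [0, 360).
wrap360 <- function(deg) deg %% 360

## Wrap angle differences (degrees) to (-180, 180].
wrap180 <- function(deg) {
  d <- (deg + 180) %% 360 - 180
  d[d == -180] <- 180
  d
}

## Minimum absolute angular distance on the circle, in [0, 180].
circ_dist_deg <- function(a, b) abs(wrap180(a - b))

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

## Analytic signal via the standard FFT construction: zero the negative
## frequencies, double the positive ones, keep DC (and Nyquist for even n).
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) so_stop("parameter", "signal too short for analytic signal")
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

## Causal (forward-only) application of an Arma filter.
filt_causal <- function(filt, x) as.numeric(signal::filter(filt, x))

## Zero-phase application (forward-backward).
filt_zerophase <- function(filt, x) as.numeric(signal::filtfilt(filt, x))

## Complex frequency response of an Arma filter at frequency f_hz.
filter_response_at <- function(filt, f_hz, fs) {
  w <- 2 * pi * f_hz / fs
  zb <- exp(-1i * w * (seq_along(filt$b) - 1))
  za <- exp(-1i * w * (seq_along(filt$a) - 1))
  sum(filt$b * zb) / sum(filt$a * za)
}

## Band-pass Butterworth design with memoisation: the predictor re-designs
## the same filter whenever the FFT-bin centre frequency is unchanged.
.filter_cache <- new.env(parent = emptyenv())
bandpass_butter <- function(order, lo_hz, hi_hz, fs) {
  key <- paste(order, lo_hz, hi_hz, fs, sep = "|")
  got <- .filter_cache[[key]]
  if (!is.null(got)) return(got)
  if (lo_hz <= 0 || hi_hz >= fs / 2 || lo_hz >= hi_hz)
    so_stop("parameter", sprintf("invalid band-pass edges [%g, %g] Hz at fs = %g", lo_hz, hi_hz, fs))
  filt <- signal::butter(order, c(lo_hz, hi_hz) / (fs / 2), type = "pass")
  .filter_cache[[key]] <- filt
  filt
}

## Next fast FFT size (highly composite) at least n.
next_fft_size <- function(n) stats::nextn(n, factors = c(2, 3, 5))
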