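# Complex Morlet wavelet time-frequency decomposition with decibel baseline
# normalisation.
#
# The wavelet family pairs 35 logarithmically spaced frequencies in
# [5, 100] Hz index-wise with 35 logarithmically spaced cycle counts in
# [4, 12]; each wavelet's Gaussian width is sigma = lambda / (2 pi f).
# This yields a temporal precision (2 sigma) of ~255 ms at 5 Hz and ~38 ms
# at 100 Hz, and a spectral precision (1 / (pi sigma)) of ~2.5 Hz and
# ~16.7 Hz respectively.

#' Morlet wavelet family specification
#'
#' @param n_freqs Number of frequencies (and cycle values).
#' @param freq_range Frequency range in Hz, log-spaced inclusively.
#' @param cycle_range Range of cycle counts lambda, log-spaced, paired
#'   index-wise with the frequencies.
#' @return Object of class `morlet_spec` with `freqs_hz`, `cycles` and
#'   `sigma_s` (`= cycles / (2 * pi * freqs_hz)`).
#' @export
morlet_spec <- function(n_freqs = 35, freq_range = c(5, 100),
                        cycle_range = c(4, 12)) {
  freqs <- exp(seq(log(freq_range[1]), log(freq_range[2]), length.out = n_freqs))
  cycles <- exp(seq(log(cycle_range[1]), log(cycle_range[2]), length.out = n_freqs))
  structure(list(freqs_hz = freqs, cycles = cycles,
                 sigma_s = cycles / (2 * pi * freqs)),
            class = "morlet_spec")
}

#' @export
print.morlet_spec <- function(x, ...) {
  cat(sprintf("<morlet_spec> %d wavelets, %.4g-%.4g Hz (log-spaced), %.3g-%.3g cycles\n",
              length(x$freqs_hz), min(x$freqs_hz), max(x$freqs_hz),
              min(x$cycles), max(x$cycles)))
  invisible(x)
}

#' Build the complex Morlet kernels
#'
#' Kernels `exp(i 2 pi f t) * exp(-t^2 / (2 sigma^2))` sampled on
#' `t` in `[-4 sigma, 4 sigma]` and L2-normalised (unit energy keeps
#' white-noise power flat across the family).
#'
#' @param spec A [morlet_spec()].
#' @param fs Sampling rate, Hz; must exceed twice the highest frequency.
#' @return List of complex kernels (odd lengths, centred at zero lag).
#' @export
build_wavelet_family <- function(spec, fs) {
  if (fs <= 2 * max(spec$freqs_hz))
    so_stop("aliasing", sprintf("fs = %g Hz too low for wavelets up to %g Hz",
                                fs, max(spec$freqs_hz)))
  lapply(seq_along(spec$freqs_hz), function(i) {
    sg <- spec$sigma_s[i]
    half <- ceiling(4 * sg * fs)
    t <- (-half:half) / fs
    k <- exp(1i * 2 * pi * spec$freqs_hz[i] * t) * exp(-t^2 / (2 * sg^2))
    k / sqrt(sum(Mod(k)^2))
  })
}

#' Temporal and spectral precision of the wavelet family
#'
#' Closed forms per frequency: temporal precision `2 * sigma` (seconds) and
#' spectral precision `1 / (pi * sigma)` (Hz).
#'
#' @param spec A [morlet_spec()].
#' @return Data frame with `freq_hz`, `cycles`, `temporal_precision_s`,
#'   `spectral_precision_hz`.
#' @export
wavelet_precisions <- function(spec) {
  data.frame(freq_hz = spec$freqs_hz,
             cycles = spec$cycles,
             temporal_precision_s = 2 * spec$sigma_s,
             spectral_precision_hz = 1 / (pi * spec$sigma_s))
}

#' Time-frequency decomposition of epoched data
#'
#' Convolves every epoch and channel with each Morlet kernel (FFT
#' convolution, zero-lag aligned), takes power as the squared complex
#' magnitude and phase as the angle (bounded in (-pi, pi\]), then decimates
#' the time axis to `fs_out` by nearest-sample selection (power and phase
#' are extracted at full rate first; no additional anti-alias filter is
#' applied to the power time courses).
#'
#' @param epochs An `epoch_set` at least as long as the longest kernel.
#' @param spec A [morlet_spec()].
#' @param fs_out Output sampling rate of the TF representation, Hz.
#' @return Object of class `so_tfr`: `power` and `phase_rad` are events x
#'   channels x freqs x time arrays; `times_s`, `freqs_hz`, `fs_out`,
#'   `conditions` describe them; `normalized` is `FALSE`.
#' @export
tf_decompose <- function(epochs, spec = morlet_spec(), fs_out = 100) {
  stopifnot(inherits(epochs, "epoch_set"))
  fs <- epochs$fs
  kernels <- build_wavelet_family(spec, fs)
  d <- dim(epochs$data)
  nt <- d[3]
  maxL <- max(lengths(kernels))
  if (nt < maxL)
    so_stop("parameter", "epoch shorter than the longest wavelet kernel")
  nfft <- next_fft_size(nt + maxL - 1)
  Kf <- lapply(kernels, function(k) fft(c(k, rep(0, nfft - length(k)))))
  halfL <- (lengths(kernels) - 1L) / 2L

  ## decimated time axis (nearest original sample)
  t_out <- seq(epochs$times_s[1], epochs$times_s[nt], by = 1 / fs_out)
  idx_out <- round((t_out - epochs$times_s[1]) * fs) + 1L
  idx_out <- pmin(idx_out, nt)

  nf <- length(kernels)
  power <- array(NA_real_, c(d[1], d[2], nf, length(idx_out)))
  phase <- array(NA_real_, c(d[1], d[2], nf, length(idx_out)))
  for (e in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      Xf <- fft(c(epochs$data[e, ch, ], rep(0, nfft - nt)))
      for (fi in seq_len(nf)) {
        conv <- fft(Xf * Kf[[fi]], inverse = TRUE) / nfft
        ## zero-lag alignment: kernel centre sits halfL ahead
        w <- conv[(halfL[fi] + 1L):(halfL[fi] + nt)][idx_out]
        power[e, ch, fi, ] <- Mod(w)^2
        phase[e, ch, fi, ] <- Arg(w)
      }
    }
  }
  structure(list(power = power, phase_rad = phase,
                 times_s = t_out, freqs_hz = spec$freqs_hz,
                 fs_out = fs_out, conditions = epochs$conditions,
                 normalized = FALSE, baseline_window_s = NULL,
                 baseline_mode = NULL),
            class = "so_tfr")
}

#' @export
print.so_tfr <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("<so_tfr> %d epoch(s) x %d channel(s) x %d freq(s) x %d time points @ %g Hz%s\n",
              d[1], d[2], d[3], d[4], x$fs_out,
              if (x$normalized) sprintf(", dB-normalised (%s baseline)", x$baseline_mode)
              else " (raw power)"))
  invisible(x)
}

#' Decibel baseline normalisation of a TFR
#'
#' Per channel and frequency, divides power by the mean baseline power
#' (default window -200 to 0 ms) computed across epochs — separately per
#' condition (`mode = "per-condition"`, appropriate when pre-stimulus power
#' differs between conditions, as between SO up and down states) or across
#' all epochs (`mode = "pooled"`) — then takes `10 * log10`. By
#' construction the across-epoch mean of the normalised power over the
#' baseline window is 0 dB. A TFR can be normalised only once; a second
#' attempt is an error, since dB values must never be re-normalised.
#'
#' @param tfr An `so_tfr` with raw power.
#' @param baseline_window_s Baseline window `(start, end)` in seconds.
#' @param mode `"per-condition"` or `"pooled"`.
#' @return The `so_tfr` with `power` replaced by dB-normalised power and
#'   `normalized = TRUE`.
#' @export
db_normalize <- function(tfr, baseline_window_s = c(-0.200, 0),
                         mode = c("per-condition", "pooled")) {
  stopifnot(inherits(tfr, "so_tfr"))
  mode <- match.arg(mode)
  if (isTRUE(tfr$normalized))
    so_stop("renormalize", "TFR is already dB-normalised; refusing to renormalise")
  ## half-open [start, end): a window ending at 0 is purely pre-stimulus
  sel <- tfr$times_s >= baseline_window_s[1] & tfr$times_s < baseline_window_s[2]
  if (!any(sel)) so_stop("parameter", "baseline window outside the TFR extent")
  d <- dim(tfr$power)
  groups <- if (mode == "per-condition" && !all(is.na(tfr$conditions)))
    split(seq_len(d[1]), tfr$conditions)
  else list(all = seq_len(d[1]))
  for (g in groups) {
    ## baseline: mean over epochs in the group and baseline samples,
    ## per channel x frequency
    bl <- apply(tfr$power[g, , , sel, drop = FALSE], c(2, 3), mean)
    if (any(bl <= 0))
      so_stop("degenerate_baseline", "non-positive baseline power")
    blrep <- array(bl, d[c(2, 3, 4)])   # recycled over time
    for (e in g) {
      slice <- array(tfr$power[e, , , ], d[c(2, 3, 4)])
      tfr$power[e, , , ] <- 10 * log10(slice / blrep)
    }
  }
  tfr$normalized <- TRUE
  tfr$baseline_window_s <- baseline_window_s
  tfr$baseline_mode <- mode
  tfr
}

#' Mean power inside a time-frequency window of interest
#'
#' Averages (dB) power over the inclusive frequency band x time window box,
#' per epoch and channel.
#'
#' @param tfr An `so_tfr`.
#' @param freq_band Frequency band `(lo, hi)` in Hz, inclusive.
#' @param time_window_s Time window `(start, end)` in seconds, inclusive.
#' @return Numeric epochs x channels matrix.
#' @export
window_average <- function(tfr, freq_band, time_window_s) {
  stopifnot(inherits(tfr, "so_tfr"))
  fsel <- tfr$freqs_hz >= freq_band[1] & tfr$freqs_hz <= freq_band[2]
  tsel <- tfr$times_s >= time_window_s[1] & tfr$times_s <= time_window_s[2]
  if (!any(fsel) || !any(tsel))
    so_stop("parameter", "empty window-of-interest selection")
  apply(tfr$power[, , fsel, tsel, drop = FALSE], c(1, 2), mean)
}

#' Named time-frequency windows of interest
#'
#' Presets for the windows used in the analyses: during sleep, a theta
#' window (5-10 Hz, 200-800 ms) and a spindle/beta window (11-27 Hz,
#' 700-1200 ms); during wakefulness, theta (5-14 Hz, 50-300 ms), alpha
#' (7-15 Hz, 500-800 ms) and gamma (55-75 Hz, 750-1100 ms).
#'
#' @param name One of `"sleep_theta"`, `"sleep_spindle_beta"`,
#'   `"wake_theta"`, `"wake_alpha"`, `"wake_gamma"`.
#' @return List with `freq_band` (Hz) and `time_window_s` (s).
#' @export
window_of_interest <- function(name = c("sleep_theta", "sleep_spindle_beta",
                                        "wake_theta", "wake_alpha",
                                        "wake_gamma")) {
  name <- match.arg(name)
  switch(name,
    sleep_theta        = list(freq_band = c(5, 10),  time_window_s = c(0.200, 0.800)),
    sleep_spindle_beta = list(freq_band = c(11, 27), time_window_s = c(0.700, 1.200)),
    wake_theta         = list(freq_band = c(5, 14),  time_window_s = c(0.050, 0.300)),
    wake_alpha         = list(freq_band = c(7, 15),  time_window_s = c(0.500, 0.800)),
    wake_gamma         = list(freq_band = c(55, 75), time_window_s = c(0.750, 1.100))
  )
}
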