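# Synthetic slow-wave-sleep EEG with ground-truth slow-oscillation phase.
#
# The generator emulates the signal regime the streaming predictor assumes:
# a dominant ~1 Hz slow oscillation (SO) whose instantaneous frequency
# wanders inside a band, with sharper down-state troughs than up-state
# peaks, on top of 1/f background noise, optionally with up-state-coupled
# spindle bursts and arousal segments in which the SO is suppressed and
# broadband noise elevated.

#' Specification of a synthetic slow-wave-sleep recording
#'
#' All amplitudes are in arbitrary EEG units (think microvolts). Phase
#' follows the sine convention throughout the package: 90 degrees is the
#' up-state peak, 270 degrees the down-state trough.
#'
#' @param duration_s Recording length in seconds.
#' @param fs Sampling rate in Hz (default 512).
#' @param so_freq_range Band (Hz) the instantaneous SO frequency is confined
#'   to by a reflecting random walk; default `c(0.6, 1.2)`.
#' @param so_freq_walk_sd Random-walk step of the instantaneous SO frequency,
#'   in Hz per SO cycle.
#' @param so_amplitude Peak amplitude of the SO component.
#' @param trough_sharpening Waveform asymmetry factor, dimensionless >= 1.
#'   1 gives a pure frequency-modulated sinusoid; larger values traverse the
#'   down state faster than the up state (phase-velocity ratio
#'   trough:peak = 2 * trough_sharpening - 1), making troughs sharper.
#' @param noise_exponent Spectral slope alpha of the 1/f^alpha background.
#' @param noise_amplitude Standard deviation of the background noise.
#' @param spindle_rate Spindle bursts per minute.
#' @param spindle_band Frequency band (Hz) spindle carriers are drawn from.
#' @param spindle_phase_coupling SO phase (degrees) burst centres lock to.
#' @param spindle_amplitude Peak envelope amplitude of a spindle burst.
#' @param arousal_intervals Optional list (or 2-column matrix/data.frame) of
#'   `(start_s, end_s)` arousal intervals: SO suppressed, broadband elevated.
#' @param n_channels Number of channels. Channel 1 is the reference channel;
#'   further channels are amplitude-scaled, lag-shifted copies plus
#'   independent noise (no realistic topography is attempted).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(duration_s = 300, fs = 512,
                       so_freq_range = c(0.6, 1.2),
                       so_freq_walk_sd = 0.05,
                       so_amplitude = 75,
                       trough_sharpening = 1.5,
                       noise_exponent = 1,
                       noise_amplitude = 20,
                       spindle_rate = 3,
                       spindle_band = c(11, 15),
                       spindle_phase_coupling = 90,
                       spindle_amplitude = 10,
                       arousal_intervals = NULL,
                       n_channels = 1,
                       seed = 1) {
  if (!is.numeric(duration_s) || duration_s <= 0)
    so_stop("parameter", "duration_s must be positive")
  if (!is.numeric(fs) || fs < 100)
    so_stop("parameter", "fs must be >= 100 Hz")
  if (trough_sharpening < 1)
    so_stop("parameter", "trough_sharpening must be >= 1")
  if (length(so_freq_range) != 2 || diff(so_freq_range) < 0 || so_freq_range[1] <= 0)
    so_stop("parameter", "so_freq_range must be an increasing positive pair")
  ar <- normalize_intervals(arousal_intervals)
  structure(list(
    duration_s = duration_s, fs = fs, so_freq_range = so_freq_range,
    so_freq_walk_sd = so_freq_walk_sd, so_amplitude = so_amplitude,
    trough_sharpening = trough_sharpening, noise_exponent = noise_exponent,
    noise_amplitude = noise_amplitude, spindle_rate = spindle_rate,
    spindle_band = spindle_band, spindle_phase_coupling = spindle_phase_coupling,
    spindle_amplitude = spindle_amplitude, arousal_intervals = ar,
    n_channels = as.integer(n_channels), seed = as.integer(seed)
  ), class = "synth_spec")
}

normalize_intervals <- function(x) {
  if (is.null(x) || (is.list(x) && length(x) == 0)) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  if (is.matrix(x)) x <- as.data.frame(x)
  if (is.data.frame(x)) {
    stopifnot(ncol(x) >= 2)
    out <- data.frame(start_s = x[[1]], end_s = x[[2]])
  } else if (is.list(x)) {
    out <- data.frame(start_s = vapply(x, `[`, 0, 1),
                      end_s = vapply(x, `[`, 0, 2))
  } else if (is.numeric(x) && length(x) == 2) {
    out <- data.frame(start_s = x[1], end_s = x[2])
  } else {
    so_stop("parameter", "cannot interpret interval specification")
  }
  if (any(out$end_s < out$start_s))
    so_stop("parameter", "interval end before start")
  out
}

## Monotone periodic phase warp controlled by trough_sharpening tau >= 1.
## psi(phi) = phi - c * sin(phi - pi/2), c = 1 - 1/tau in (0, 1):
## fixes 90 and 270 degrees, speeds the trough up by (1 + c) and slows the
## peak down by (1 - c).
warp_phase <- function(phi_rad, tau) {
  cc <- 1 - 1 / tau
  phi_rad - cc * sin(phi_rad - pi / 2)
}

## Reflecting random walk inside [lo, hi] by triangle-wave folding of an
## unconstrained cumulative walk (exact reflection).
reflect_walk <- function(free, lo, hi) {
  w <- hi - lo
  y <- (free - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}

## 1/f^alpha noise by spectral shaping of white Gaussian noise; returned with
## unit standard deviation (caller scales).
one_over_f_noise <- function(n, alpha) {
  white <- rnorm(n)
  X <- fft(white)
  f_idx <- c(0, seq_len(n - 1))
  f_idx <- pmin(f_idx, n - f_idx)       # symmetric frequency index
  wgt <- ifelse(f_idx == 0, 0, f_idx^(-alpha / 2))
  x <- Re(fft(X * wgt, inverse = TRUE) / n)
  s <- sd(x)
  if (s == 0) return(x)
  x / s
}

#' Generate a synthetic slow-wave-sleep recording with ground truth
#'
#' Returns the multi-channel signal together with the per-sample true SO
#' phase and instantaneous frequency of the reference channel, plus the
#' arousal intervals rendered as an event table.
#'
#' @param spec A [synth_spec()].
#' @return A list of class `so_synth` with elements:
#'   \describe{
#'     \item{recording}{`so_recording`: samples x channels matrix plus `fs`.}
#'     \item{truth}{`so_ground_truth`: `phase_deg` in \[0, 360) (sine
#'       convention, 90 = up-state peak) and `inst_freq_hz`, per sample.}
#'     \item{events}{Event table of arousal onsets (`label = "arousal"`),
#'       one row per interval.}
#'     \item{arousals}{Data frame of `(start_s, end_s)` arousal intervals.}
#'     \item{spec}{The input spec.}
#'   }
#' @examples
#' syn <- generate_recording(synth_spec(duration_s = 30, seed = 1))
#' str(syn$recording$data)
#' @export
generate_recording <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  fs <- spec$fs
  n <- round(spec$duration_s * fs)
  set.seed(spec$seed)

  lo <- spec$so_freq_range[1]; hi <- spec$so_freq_range[2]
  f_mid <- mean(spec$so_freq_range)
  if (hi > lo && spec$so_freq_walk_sd > 0) {
    ## per-sample step chosen so the variance accrued over one (mid-band)
    ## cycle equals so_freq_walk_sd^2
    step_sd <- spec$so_freq_walk_sd * sqrt(f_mid / fs)
    f0_start <- runif(1, lo + 0.25 * (hi - lo), hi - 0.25 * (hi - lo))
    free <- f0_start + cumsum(c(0, rnorm(n - 1, 0, step_sd)))
    inst_freq <- reflect_walk(free, lo, hi)
  } else {
    inst_freq <- rep(f_mid, n)
  }

  phi0 <- runif(1, 0, 2 * pi)
  phi <- phi0 + 2 * pi * cumsum(inst_freq) / fs   # unwrapped true phase (rad)
  phase_deg <- wrap360(rad2deg(phi))

  so <- spec$so_amplitude * sin(warp_phase(phi, spec$trough_sharpening))

  ## up-state-coupled spindle bursts
  spindles <- numeric(n)
  if (spec$spindle_rate > 0 && spec$spindle_amplitude > 0) {
    target <- deg2rad(spec$spindle_phase_coupling)
    ## samples where the true phase crosses the coupling phase (rising)
    ph_rel <- (phi - target) %% (2 * pi)
    cross <- which(diff(ph_rel) < -pi) + 1L
    n_bursts <- min(length(cross), round(spec$spindle_rate * spec$duration_s / 60))
    if (n_bursts > 0) {
      centers <- sort(sample(cross, n_bursts))
      sigma_sp <- 0.15  # s; burst envelope SD (~0.6 s visible burst)
      half <- round(4 * sigma_sp * fs)
      for (c0 in centers) {
        f_sp <- runif(1, spec$spindle_band[1], spec$spindle_band[2])
        th <- runif(1, 0, 2 * pi)
        idx <- max(1, c0 - half):min(n, c0 + half)
        t_rel <- (idx - c0) / fs
        spindles[idx] <- spindles[idx] +
          spec$spindle_amplitude * exp(-t_rel^2 / (2 * sigma_sp^2)) *
          sin(2 * pi * f_sp * t_rel + th)
      }
    }
  }

  noise <- if (spec$noise_amplitude > 0)
    spec$noise_amplitude * one_over_f_noise(n, spec$noise_exponent)
  else numeric(n)

  ## arousals: SO nearly silenced, broadband noise elevated (hard-edged
  ## segments; the offline analysis excludes a 2 s margin around them anyway)
  ar <- spec$arousal_intervals
  if (nrow(ar) > 0) {
    so_gain <- rep(1, n); noise_gain <- rep(1, n)
    for (k in seq_len(nrow(ar))) {
      i0 <- max(1L, round(ar$start_s[k] * fs) + 1L)
      i1 <- min(n, round(ar$end_s[k] * fs))
      if (i1 < i0) next
      so_gain[i0:i1] <- 0.05
      noise_gain[i0:i1] <- 3
    }
    so <- so * so_gain
    spindles <- spindles * so_gain
    noise <- noise * noise_gain
  }

  ref <- so + spindles + noise
  nc <- spec$n_channels
  data <- matrix(0, n, nc)
  data[, 1] <- ref
  if (nc > 1) {
    for (ch in 2:nc) {
      lag <- round(0.01 * fs) * (ch - 1)
      shifted <- c(rep(ref[1], lag), ref[seq_len(n - lag)])
      extra <- if (spec$noise_amplitude > 0)
        spec$noise_amplitude * 0.5 * one_over_f_noise(n, spec$noise_exponent)
      else numeric(n)
      data[, ch] <- 0.85^(ch - 1) * shifted + extra
    }
  }
  colnames(data) <- paste0("ch", seq_len(nc))

  events <- if (nrow(ar) > 0) {
    data.frame(sample = round(ar$start_s * fs) + 1L,
               label = "arousal", condition = NA_character_,
               stringsAsFactors = FALSE)
  } else empty_event_table()

  structure(list(
    recording = new_recording(data, fs),
    truth = structure(list(phase_deg = phase_deg, inst_freq_hz = inst_freq,
                           fs = fs), class = "so_ground_truth"),
    events = events,
    arousals = ar,
    spec = spec
  ), class = "so_synth")
}

#' Construct a recording object
#'
#' @param data Numeric vector (single channel) or samples x channels matrix.
#' @param fs Sampling rate in Hz.
#' @param channel_names Optional channel names.
#' @return An object of class `so_recording`.
#' @export
new_recording <- function(data, fs, channel_names = NULL) {
  if (is.vector(data)) data <- matrix(data, ncol = 1)
  if (!is.null(channel_names)) colnames(data) <- channel_names
  if (is.null(colnames(data))) colnames(data) <- paste0("ch", seq_len(ncol(data)))
  structure(list(data = data, fs = fs), class = "so_recording")
}

#' @export
print.so_recording <- function(x, ...) {
  cat(sprintf("<so_recording> %d samples x %d channel(s) @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, nrow(x$data) / x$fs))
  invisible(x)
}

#' @export
print.so_synth <- function(x, ...) {
  print(x$recording)
  cat(sprintf("  ground truth SO phase attached; %d arousal interval(s)\n",
              nrow(x$arousals)))
  invisible(x)
}

#' Plot a stretch of a recording
#'
#' @param x An `so_recording`.
#' @param t_range Time range (s) to display.
#' @param channel Channel index.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.so_recording <- function(x, t_range = c(0, min(30, nrow(x$data) / x$fs)),
                              channel = 1, ...) {
  i0 <- max(1L, round(t_range[1] * x$fs) + 1L)
  i1 <- min(nrow(x$data), round(t_range[2] * x$fs))
  tt <- (i0:i1 - 1) / x$fs
  graphics::plot(tt, x$data[i0:i1, channel], type = "l",
                 xlab = "time (s)", ylab = "amplitude", ...)
  invisible(x)
}

#' A K-complex-like biphasic template
#'
#' Sharp negative deflection followed by a slower positive rebound,
#' peak-normalised to unit absolute amplitude. Used to inject known evoked
#' responses into synthetic recordings.
#'
#' @param fs Sampling rate in Hz.
#' @param duration_s Template length in seconds.
#' @return Numeric waveform of length `round(duration_s * fs)`.
#' @export
kcomplex_template <- function(fs = 512, duration_s = 1.5) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  w <- -1.0 * exp(-(t - 0.55)^2 / (2 * 0.09^2)) +
        0.6 * exp(-(t - 0.95)^2 / (2 * 0.16^2)) +
        0.25 * exp(-(t - 0.25)^2 / (2 * 0.08^2))
  w / max(abs(w))
}

#' Add a known evoked response at event onsets
#'
#' Adds `scale * template` to every channel starting at each event sample.
#' Purely additive, so injections at disjoint events are order-independent.
#'
#' @param recording An `so_recording`.
#' @param events Event table with a `sample` column (1-based onsets).
#' @param template Numeric waveform.
#' @param scale Multiplier applied to the template.
#' @return The modified `so_recording`.
#' @export
inject_evoked_response <- function(recording, events, template, scale = 1) {
  stopifnot(inherits(recording, "so_recording"))
  n <- nrow(recording$data)
  L <- length(template)
  for (s in events$sample) {
    if (s < 1 || s + L - 1 > n)
      so_stop("index", sprintf("event at sample %d extends beyond recording", s))
  }
  if (scale == 0) return(recording)
  for (s in events$sample) {
    idx <- s:(s + L - 1)
    recording$data[idx, ] <- recording$data[idx, ] + scale * template
  }
  recording
}

#' Simulate two-alternative forced-choice behaviour
#'
#' Each subject judges `n_pairs_per_contrast` sound pairs per contrast and
#' picks the first category with probability `p_first` (Bernoulli per pair);
#' chance performance is 50%.
#'
#' @param n_subjects Number of subjects.
#' @param n_pairs_per_contrast Pairs per contrast per subject.
#' @param p_first Probability of choosing the first category of a contrast.
#' @param seed Integer seed.
#' @param contrasts Character vector of contrast names.
#' @return Data frame with columns `subject`, `contrast`, `percent_first`.
#' @export
generate_behavior <- function(n_subjects = 12, n_pairs_per_contrast = 20,
                              p_first = 0.5, seed = 1,
                              contrasts = c("up_vs_down", "up_vs_new",
                                            "down_vs_new")) {
  if (n_pairs_per_contrast <= 0)
    so_stop("parameter", "n_pairs_per_contrast must be positive")
  if (p_first < 0 || p_first > 1)
    so_stop("parameter", "p_first must lie in [0, 1]")
  set.seed(seed)
  out <- expand.grid(subject = seq_len(n_subjects), contrast = contrasts,
                     stringsAsFactors = FALSE)
  out$percent_first <- 100 * rbinom(nrow(out), n_pairs_per_contrast, p_first) /
    n_pairs_per_contrast
  out[order(out$subject), c("subject", "contrast", "percent_first")]
}

empty_event_table <- function() {
  data.frame(sample = integer(0), label = character(0),
             condition = character(0), stringsAsFactors = FALSE)
}
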