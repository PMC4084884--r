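# Streaming slow-oscillation phase prediction.
#
# The algorithm buffers the most recent samples, estimates the momentary SO
# frequency as the FFT amplitude argmax inside a search band, band-passes
# the buffer with a causal order-1 Butterworth centred on that frequency,
# takes the Hilbert analytic phase (sine convention: 90 deg = up-state
# peak), least-squares-fits a unit sine to sin(phase) over a late window of
# the buffer, extrapolates it forward, and emits a trigger at the earliest
# requested target phase — subject to a band-power criterion, a fit-quality
# criterion, a prediction-horizon limit, and a post-trigger time-out.

#' Configuration of the streaming phase predictor
#'
#' Defaults correspond to a 512 Hz single-channel recording: a 5000-sample
#' (~10 s) buffer, an SO search band of 0.6-1.2 Hz, an order-1 Butterworth
#' band-pass of 1 Hz bandwidth centred on the momentary SO frequency, sine
#' fitting on the 80-95% stretch of the buffer (~1.5 s, clear of filter
#' edge artifacts at the buffer end), SO-band power at least 0.6 of total
#' power, mean-squared fit residual at most 0.1, predictions at most 250 ms
#' ahead, a 10000-sample (~20 s) post-trigger time-out, and dual targets at
#' 90 deg (up state) and 270 deg (down state). `playback_lead_s` is half the
#' stimulus duration: triggers are scheduled early so the stimulus midpoint
#' lands on the target phase (250 ms for a 500 ms sound clip).
#'
#' @param fs Sampling rate, Hz.
#' @param buffer_len Analysis buffer length, samples.
#' @param so_search_band Band (Hz) searched for the momentary SO frequency.
#' @param filter_order Butterworth order of the online band-pass.
#' @param filter_bandwidth_hz Bandwidth (Hz) of the online band-pass.
#' @param fit_window_frac Fractions of the buffer delimiting the sine-fit
#'   window, default `c(0.80, 0.95)`.
#' @param power_ratio_min Minimum SO-band / total (non-DC) power ratio.
#' @param fit_error_max Maximum mean-squared sine-fit residual.
#' @param horizon_max_s Maximum look-ahead of a prediction, seconds.
#' @param timeout_samples Samples after a trigger during which no new
#'   prediction is attempted.
#' @param target_phases_deg Target phases (degrees, sine convention). On a
#'   tie in predicted arrival the earlier entry of this vector wins.
#' @param playback_lead_s Lead subtracted (as phase, frequency-dependently)
#'   so the stimulus midpoint coincides with the target phase.
#' @param fit_raw_analytic If `TRUE`, the sine (with free amplitude) is
#'   fitted to the raw band-passed signal instead of the unit-amplitude
#'   sin(phase) trace, and the fit error is the residual mean square
#'   relative to the signal mean square. Default `FALSE` (normalised fit):
#'   the analytic-phase signal has constant cycle-to-cycle amplitude, so
#'   SO-to-SO amplitude differences do not influence the fit.
#' @return Object of class `predictor_config`.
#' @export
predictor_config <- function(fs = 512, buffer_len = 5000,
                             so_search_band = c(0.6, 1.2),
                             filter_order = 1, filter_bandwidth_hz = 1.0,
                             fit_window_frac = c(0.80, 0.95),
                             power_ratio_min = 0.6, fit_error_max = 0.1,
                             horizon_max_s = 0.250, timeout_samples = 10000,
                             target_phases_deg = c(90, 270),
                             playback_lead_s = 0.250,
                             fit_raw_analytic = FALSE) {
  if (!(fit_window_frac[1] > 0 && fit_window_frac[1] < fit_window_frac[2] &&
        fit_window_frac[2] <= 1))
    so_stop("parameter", "need 0 < fit_window_frac[1] < fit_window_frac[2] <= 1")
  if (so_search_band[1] <= 0 || so_search_band[2] >= fs / 2)
    so_stop("parameter", "so_search_band must lie inside (0, fs/2)")
  if (length(target_phases_deg) < 1)
    so_stop("parameter", "at least one target phase required")
  structure(list(
    fs = fs, buffer_len = as.integer(buffer_len),
    so_search_band = so_search_band, filter_order = filter_order,
    filter_bandwidth_hz = filter_bandwidth_hz,
    fit_window_frac = fit_window_frac, power_ratio_min = power_ratio_min,
    fit_error_max = fit_error_max, horizon_max_s = horizon_max_s,
    timeout_samples = as.integer(timeout_samples),
    target_phases_deg = wrap360(target_phases_deg),
    playback_lead_s = playback_lead_s,
    fit_raw_analytic = isTRUE(fit_raw_analytic)
  ), class = "predictor_config")
}

#' @export
print.predictor_config <- function(x, ...) {
  cat("<predictor_config>\n")
  cat(sprintf("  fs %g Hz, buffer %d samples (%.1f s), SO band %.2f-%.2f Hz\n",
              x$fs, x$buffer_len, x$buffer_len / x$fs,
              x$so_search_band[1], x$so_search_band[2]))
  cat(sprintf("  criteria: power >= %.2f, fit error <= %.2f, horizon <= %g ms, timeout %d samples\n",
              x$power_ratio_min, x$fit_error_max, 1000 * x$horizon_max_s,
              x$timeout_samples))
  cat(sprintf("  targets: %s deg, playback lead %g ms\n",
              paste(x$target_phases_deg, collapse = ", "),
              1000 * x$playback_lead_s))
  invisible(x)
}

## FFT bins inside the search band (inclusive), excluding DC.
band_bins <- function(cfg) {
  df <- cfg$fs / cfg$buffer_len
  k <- seq_len(floor(cfg$buffer_len / 2))        # bins 1..N/2 (cycles/buffer)
  f <- k * df
  list(k = k, f = f,
       in_band = f >= cfg$so_search_band[1] & f <= cfg$so_search_band[2])
}

#' Momentary SO centre frequency of a buffer
#'
#' The FFT bin with the largest amplitude coefficient inside the SO search
#' band; the bin spacing is `fs / buffer_len` (0.1024 Hz at the defaults).
#'
#' @param buffer Numeric vector of exactly `cfg$buffer_len` samples (oldest
#'   first), or a `predictor_state` whose buffer is full.
#' @param cfg A [predictor_config()].
#' @return Centre frequency in Hz.
#' @export
estimate_center_frequency <- function(buffer, cfg) {
  buf <- as_buffer(buffer, cfg)
  sp <- Mod(fft(buf))
  bb <- band_bins(cfg)
  amp <- sp[bb$k + 1L][bb$in_band]
  bb$f[bb$in_band][which.max(amp)]
}

#' SO-band power as a fraction of total power
#'
#' Sum of FFT power over bins inside the search band divided by the sum
#' over all non-DC bins up to Nyquist (amplifier offset carries no
#' physiological information, hence DC is excluded).
#'
#' @inheritParams estimate_center_frequency
#' @return Dimensionless ratio in \[0, 1\].
#' @export
so_power_ratio <- function(buffer, cfg) {
  buf <- as_buffer(buffer, cfg)
  p <- Mod(fft(buf))^2
  bb <- band_bins(cfg)
  tot <- sum(p[bb$k + 1L])
  if (tot == 0) so_stop("undefined_ratio", "all-zero buffer: power ratio undefined")
  sum(p[bb$k + 1L][bb$in_band]) / tot
}

## One FFT serving both the centre frequency and the power ratio (the
## streaming path evaluates both every sample).
spectral_snapshot <- function(buf, cfg) {
  p <- Mod(fft(buf))^2
  bb <- band_bins(cfg)
  pk <- p[bb$k + 1L]
  tot <- sum(pk)
  if (tot == 0) return(NULL)
  in_band <- pk[bb$in_band]
  list(f0 = bb$f[bb$in_band][which.max(in_band)],
       power_ratio = sum(in_band) / tot)
}

#' Online instantaneous SO phase of a buffer
#'
#' Band-passes the buffer with a causal (forward-only) order-1 Butterworth
#' of the configured bandwidth centred on `f0`, derives the analytic signal
#' via the Hilbert transform, and converts its angle to the sine convention
#' (+90 deg, so the phase is 90 deg at band-passed signal peaks). With
#' `correct_lag = TRUE` the filter's phase lag at `f0` (from its frequency
#' response) is additionally subtracted so the trace refers to the
#' unfiltered signal; the streaming path applies this correction before
#' sine fitting.
#'
#' @inheritParams estimate_center_frequency
#' @param f0 Centre frequency in Hz, inside the search band.
#' @param correct_lag Subtract the filter's phase lag at `f0` (default
#'   `FALSE`: the trace describes the band-passed signal itself).
#' @return Per-sample phase trace in degrees, wrapped to \[0, 360).
#' @export
instantaneous_phase <- function(buffer, f0, cfg, correct_lag = FALSE) {
  buf <- as_buffer(buffer, cfg)
  if (f0 < cfg$so_search_band[1] || f0 > cfg$so_search_band[2])
    so_stop("parameter", sprintf("f0 = %g Hz outside the SO search band", f0))
  bp <- online_bandpass(buf, f0, cfg)
  ## degeneracy is judged away from the filter's startup transient (the
  ## stretch that actually feeds the sine fit)
  tail_idx <- max(1L, round(cfg$fit_window_frac[1] * cfg$buffer_len)):cfg$buffer_len
  if (max(abs(bp$y[tail_idx])) < 1e-9 * max(1e-300, max(abs(buf))))
    so_stop("undefined_phase", "band-passed buffer is (near) zero: phase undefined")
  ana <- analytic_signal(bp$y)
  corr <- if (correct_lag) bp$lag_deg else 0
  wrap360(rad2deg(Arg(ana)) + 90 - corr)
}

online_bandpass <- function(buf, f0, cfg) {
  half <- cfg$filter_bandwidth_hz / 2
  filt <- bandpass_butter(cfg$filter_order, f0 - half, f0 + half, cfg$fs)
  y <- filt_causal(filt, buf)
  lag_deg <- rad2deg(Arg(filter_response_at(filt, f0, cfg$fs)))
  list(y = y, filt = filt, lag_deg = lag_deg)
}

#' Least-squares sine fit to the phase trace over the fit window
#'
#' Fits \eqn{s(t) = \sin(2\pi f_0 t + \phi)} to the unit-amplitude signal
#' `sin(phase_trace)` over the configured late stretch of the buffer only
#' (the newest ~5% are excluded because of filter edge artifacts). The fit
#' error is the mean squared residual on the unit-amplitude signal; the
#' fitted phase is evaluated at the newest buffer sample.
#'
#' @param phase_trace Per-sample phase in degrees over a full buffer (as
#'   returned by [instantaneous_phase()]), or, with
#'   `cfg$fit_raw_analytic = TRUE`, the raw band-passed signal.
#' @param f0 Centre frequency in Hz.
#' @param cfg A [predictor_config()].
#' @param power_ratio Optional, stored in the result for reporting.
#' @return Object of class `sine_fit` with `center_freq_hz`,
#'   `fitted_phase_deg` (phase of the fitted sine at the newest sample),
#'   `fit_error` and `power_ratio`.
#' @export
fit_reference_sine <- function(phase_trace, f0, cfg, power_ratio = NA_real_) {
  L <- cfg$buffer_len
  if (length(phase_trace) != L)
    so_stop("parameter", "phase trace must cover exactly one buffer")
  i0 <- max(1L, round(cfg$fit_window_frac[1] * L))
  i1 <- min(L, round(cfg$fit_window_frac[2] * L))
  if ((i1 - i0) / cfg$fs < 1 / f0)
    so_stop("degenerate_fit",
            sprintf("fit window (%.3f s) shorter than one SO cycle at %.3f Hz",
                    (i1 - i0) / cfg$fs, f0))
  idx <- i0:i1
  tt <- (idx - 1) / cfg$fs
  w <- 2 * pi * f0
  if (cfg$fit_raw_analytic) {
    y <- phase_trace[idx]
    X <- cbind(sin(w * tt), cos(w * tt))
    ab <- qr.solve(X, y)
    phi <- atan2(ab[2], ab[1])
    resid <- y - X %*% ab
    ms <- mean(y^2)
    err <- if (ms > 0) mean(resid^2) / ms else Inf
  } else {
    y <- sin(deg2rad(phase_trace[idx]))
    a <- sum(y * sin(w * tt)); b <- sum(y * cos(w * tt))
    phi <- atan2(b, a)
    err <- mean((y - sin(w * tt + phi))^2)
  }
  t_now <- (L - 1) / cfg$fs
  structure(list(center_freq_hz = f0,
                 fitted_phase_deg = wrap360(rad2deg(w * t_now + phi)),
                 fit_error = err, power_ratio = power_ratio),
            class = "sine_fit")
}

#' @export
print.sine_fit <- function(x, ...) {
  cat(sprintf("<sine_fit> f0 = %.4f Hz, phase(now) = %.1f deg, fit error = %.4g, power ratio = %.3f\n",
              x$center_freq_hz, x$fitted_phase_deg, x$fit_error, x$power_ratio))
  invisible(x)
}

#' Frequency-dependent playback-lead compensation
#'
#' A stimulus of duration `2 * lead_s` started at the returned phase has its
#' midpoint on `target_phase_deg`: slower SOs need a smaller phase lead
#' (playback starts later in phase), faster SOs a larger one.
#'
#' @param target_phase_deg Target phase in degrees.
#' @param f0 SO frequency in Hz.
#' @param lead_s Lead time in seconds (half the stimulus duration).
#' @return Adjusted phase in degrees, `(target - 360 * f0 * lead_s) mod 360`.
#' @export
compensate_lead <- function(target_phase_deg, f0, lead_s) {
  if (any(lead_s < 0)) so_stop("parameter", "lead_s must be >= 0")
  wrap360(target_phase_deg - 360 * f0 * lead_s)
}

#' Earliest future occurrence of a target phase on the extrapolated sine
#'
#' Phase advances linearly from the fitted phase at rate `360 * f0` deg/s;
#' each adjusted target is reached after
#' `((target - fitted) mod 360) / (360 * f0)` seconds. The earliest target
#' wins (ties broken toward the earlier entry of `adjusted_deg`); if even
#' that lies beyond the horizon, no prediction is made.
#'
#' @param fit A `sine_fit`.
#' @param adjusted_deg Adjusted (lead-compensated) target phases, degrees.
#' @param now_sample Absolute index of the newest sample.
#' @param cfg A [predictor_config()].
#' @return `NULL`, or a list with `dt_s`, `trigger_sample`
#'   (`now_sample + round(dt_s * fs)`) and `target_index`.
#' @export
predict_target_time <- function(fit, adjusted_deg, now_sample, cfg) {
  if (length(adjusted_deg) < 1) so_stop("parameter", "empty target list")
  dphi <- wrap360(adjusted_deg - fit$fitted_phase_deg)
  dphi[dphi < 1e-9] <- 360      # "first occurrence": now does not count
  dt <- dphi / (360 * fit$center_freq_hz)
  j <- which.min(dt)                     # ties: earlier list entry wins
  if (dt[j] > cfg$horizon_max_s) return(NULL)
  list(dt_s = dt[j],
       trigger_sample = now_sample + round(dt[j] * cfg$fs),
       target_index = j)
}

#' Create a fresh predictor state
#'
#' The state holds the rolling sample buffer, trigger bookkeeping, and any
#' pending (scheduled but not yet emitted) prediction. It is an environment
#' and is modified in place by [predictor_step()].
#'
#' @param cfg A [predictor_config()].
#' @return Object of class `predictor_state`.
#' @export
new_predictor_state <- function(cfg) {
  st <- new.env(parent = emptyenv())
  st$cfg <- cfg
  st$ring <- numeric(cfg$buffer_len)
  st$pos <- 0L                 # write position within ring
  st$n <- 0L                   # absolute index of newest sample
  st$last_trigger <- NA_integer_
  st$pending <- NULL           # list(trigger_sample, ...) awaiting emission
  class(st) <- "predictor_state"
  st
}

#' @export
print.predictor_state <- function(x, ...) {
  cat(sprintf("<predictor_state> %d sample(s) seen; %s; %s\n", x$n,
              if (is.null(x$pending)) "armed" else "prediction pending",
              if (is.na(x$last_trigger)) "no trigger yet"
              else sprintf("last trigger at sample %d", x$last_trigger)))
  invisible(x)
}

as_buffer <- function(buffer, cfg) {
  if (inherits(buffer, "predictor_state")) {
    if (buffer$n < cfg$buffer_len)
      so_stop("not_ready", "buffer not yet full")
    return(ordered_buffer(buffer))
  }
  buf <- as.numeric(buffer)
  if (length(buf) != cfg$buffer_len)
    so_stop("not_ready", sprintf("need exactly %d samples, got %d",
                                 cfg$buffer_len, length(buf)))
  buf
}

ordered_buffer <- function(st) {
  p <- st$pos
  if (p == st$cfg$buffer_len) st$ring else c(st$ring[(p + 1L):st$cfg$buffer_len],
                                             st$ring[seq_len(p)])
}

#' Advance the predictor by one sample
#'
#' Appends a sample to the state's buffer and runs one step of the decision
#' logic: while a prediction is pending, analysis is suspended and the
#' trigger is emitted once the stream reaches the scheduled sample; while
#' within the post-trigger time-out, nothing is evaluated; otherwise, once
#' the buffer is full, the band-power and fit-quality criteria are checked
#' and, if both hold, a prediction is attempted within the horizon.
#'
#' @param state A `predictor_state` (modified in place).
#' @param new_sample The next signal sample.
#' @param cfg A [predictor_config()]; must match the one in the state.
#' @return `NULL`, or — at the emission sample — a one-row data frame with
#'   `sample` (trigger), `decision_sample`, `targeted_phase_deg`,
#'   `adjusted_phase_deg` and `center_freq_hz`.
#' @export
predictor_step <- function(state, new_sample, cfg = state$cfg) {
  st <- state
  st$n <- st$n + 1L
  p <- st$pos + 1L
  if (p > cfg$buffer_len) p <- 1L
  st$ring[p] <- new_sample
  st$pos <- p

  ## pending prediction: suspend analysis, emit when due
  if (!is.null(st$pending)) {
    if (st$n >= st$pending$trigger_sample) {
      ev <- st$pending
      st$pending <- NULL
      st$last_trigger <- st$n
      return(data.frame(sample = st$n,
                        decision_sample = ev$decision_sample,
                        targeted_phase_deg = ev$targeted_phase_deg,
                        adjusted_phase_deg = ev$adjusted_phase_deg,
                        center_freq_hz = ev$center_freq_hz))
    }
    return(NULL)
  }
  if (st$n < cfg$buffer_len) return(NULL)
  if (!is.na(st$last_trigger) && st$n - st$last_trigger < cfg$timeout_samples)
    return(NULL)

  buf <- ordered_buffer(st)
  snap <- spectral_snapshot(buf, cfg)
  if (is.null(snap) || snap$power_ratio < cfg$power_ratio_min) return(NULL)

  fit <- tryCatch({
    if (cfg$fit_raw_analytic) {
      bp <- online_bandpass(buf, snap$f0, cfg)
      fit_reference_sine(bp$y, snap$f0, cfg, power_ratio = snap$power_ratio)
    } else {
      ## lag-corrected phase: the fitted/extrapolated phase then refers to
      ## the unfiltered signal (group-delay handling, done before fitting)
      ph <- instantaneous_phase(buf, snap$f0, cfg, correct_lag = TRUE)
      fit_reference_sine(ph, snap$f0, cfg, power_ratio = snap$power_ratio)
    }
  }, sophase_error = function(e) NULL)
  if (is.null(fit) || fit$fit_error > cfg$fit_error_max) return(NULL)

  adjusted <- compensate_lead(cfg$target_phases_deg, snap$f0,
                              cfg$playback_lead_s)
  pred <- predict_target_time(fit, adjusted, st$n, cfg)
  if (is.null(pred)) return(NULL)

  ev <- list(trigger_sample = pred$trigger_sample,
             decision_sample = st$n,
             targeted_phase_deg = cfg$target_phases_deg[pred$target_index],
             adjusted_phase_deg = adjusted[pred$target_index],
             center_freq_hz = snap$f0)
  if (ev$trigger_sample <= st$n) {       # due immediately
    st$last_trigger <- st$n
    return(data.frame(sample = st$n,
                      decision_sample = ev$decision_sample,
                      targeted_phase_deg = ev$targeted_phase_deg,
                      adjusted_phase_deg = ev$adjusted_phase_deg,
                      center_freq_hz = ev$center_freq_hz))
  }
  st$pending <- ev
  NULL
}

#' Replay a recording through the streaming predictor
#'
#' Feeds the selected channel sample by sample through [predictor_step()]
#' and collects the emitted triggers. Fully deterministic: the same
#' recording and configuration always give the same trigger list.
#'
#' @param recording An `so_recording` (or numeric vector; `cfg$fs` then
#'   gives the sampling rate).
#' @param cfg A [predictor_config()].
#' @param channel Channel index for multi-channel recordings. Required if
#'   the recording has more than one channel.
#' @param events_path Optional path; if given, the trigger table is written
#'   as tab-separated text (see [write_events()] for the format).
#' @return Object of class `so_triggers`: a data frame with one row per
#'   trigger (`sample`, `decision_sample`, `targeted_phase_deg`,
#'   `adjusted_phase_deg`, `center_freq_hz`).
#' @examples
#' syn <- generate_recording(synth_spec(duration_s = 60, seed = 2))
#' cfg <- predictor_config()
#' trig <- run_stream(syn$recording, cfg)
#' trig
#' @export
run_stream <- function(recording, cfg, channel = NULL, events_path = NULL) {
  if (inherits(recording, "so_recording")) {
    if (ncol(recording$data) > 1 && is.null(channel))
      so_stop("parameter", "multi-channel recording: a channel must be selected")
    x <- recording$data[, if (is.null(channel)) 1L else channel]
    if (recording$fs != cfg$fs)
      so_stop("parameter", "recording and config sampling rates differ")
  } else {
    x <- as.numeric(recording)
  }
  st <- new_predictor_state(cfg)
  out <- vector("list", 64L)
  k <- 0L
  for (i in seq_along(x)) {
    ev <- predictor_step(st, x[i], cfg)
    if (!is.null(ev)) {
      k <- k + 1L
      if (k > length(out)) out <- c(out, vector("list", length(out)))
      out[[k]] <- ev
    }
  }
  trig <- if (k > 0) do.call(rbind, out[seq_len(k)]) else
    data.frame(sample = integer(0), decision_sample = integer(0),
               targeted_phase_deg = numeric(0), adjusted_phase_deg = numeric(0),
               center_freq_hz = numeric(0))
  class(trig) <- c("so_triggers", "data.frame")
  if (!is.null(events_path)) {
    tab <- data.frame(sample = trig$sample,
                      label = "stimulus",
                      condition = ifelse(circ_dist_deg(trig$targeted_phase_deg, 90) <=
                                           circ_dist_deg(trig$targeted_phase_deg, 270),
                                         "up", "down"),
                      stringsAsFactors = FALSE)
    write_events(tab, events_path,
                 extra = trig[, c("targeted_phase_deg", "adjusted_phase_deg",
                                  "center_freq_hz")])
  }
  trig
}

#' @export
print.so_triggers <- function(x, ...) {
  cat(sprintf("<so_triggers> %d trigger(s)\n", nrow(x)))
  if (nrow(x) > 0) {
    tab <- table(x$targeted_phase_deg)
    cat("  per target phase (deg):",
        paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
    print.data.frame(utils::head(as.data.frame(x), 10))
    if (nrow(x) > 10) cat(sprintf("  ... %d more rows\n", nrow(x) - 10))
  }
  invisible(x)
}
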