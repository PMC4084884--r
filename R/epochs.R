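# Event exclusion, epoching, baseline correction, ERPs, and SO-phase-matched
# fake-event construction.

#' Exclude events near arousal intervals
#'
#' Removes events whose time falls within `margin_s` of any arousal
#' interval, i.e. inside `[start - margin, end + margin]`.
#'
#' @param events Event table with a `sample` column.
#' @param arousals Data frame / matrix / list of `(start_s, end_s)` pairs.
#' @param fs Sampling rate, Hz.
#' @param margin_s Exclusion margin around each interval, seconds.
#' @return The filtered event table.
#' @export
exclude_arousal_events <- function(events, arousals, fs, margin_s = 2.0) {
  ar <- normalize_intervals(arousals)
  if (nrow(ar) == 0 || nrow(events) == 0) return(events)
  t_ev <- (events$sample - 1) / fs
  drop <- rep(FALSE, nrow(events))
  for (k in seq_len(nrow(ar))) {
    drop <- drop | (t_ev >= ar$start_s[k] - margin_s &
                    t_ev <= ar$end_s[k] + margin_s)
  }
  events[!drop, , drop = FALSE]
}

#' Cut a recording into event-locked epochs
#'
#' Copies the half-open window `[event + t0*fs, event + t1*fs)` around each
#' event (time 0 = event onset sample). Events with insufficient history or
#' future are reported in `$skipped`, not silently dropped. If the event
#' table carries an `onset_shift_s` column, it is added per event before
#' windowing (used to re-lock epochs to actual sound onset when stimuli
#' were zero-padded).
#'
#' @param recording An `so_recording`.
#' @param events Event table with `sample` (and optionally `condition`,
#'   `onset_shift_s`) columns.
#' @param t0_s Epoch start relative to the event, seconds (default -1).
#' @param t1_s Epoch end (exclusive), seconds (default +2.5).
#' @return Object of class `epoch_set`: `data` is an events x channels x
#'   time array; `times_s` gives per-sample latencies; `conditions` carries
#'   the per-epoch condition labels; `skipped` the near-edge events.
#' @export
epoch_recording <- function(recording, events, t0_s = -1.0, t1_s = 2.5) {
  stopifnot(inherits(recording, "so_recording"))
  fs <- recording$fs
  n <- nrow(recording$data)
  nt <- round((t1_s - t0_s) * fs)
  rel <- round(t0_s * fs) + 0:(nt - 1)
  onset <- events$sample
  if (!is.null(events$onset_shift_s)) onset <- onset + round(events$onset_shift_s * fs)
  ok <- onset + rel[1] >= 1 & onset + rel[nt] <= n
  kept <- which(ok)
  nc <- ncol(recording$data)
  data <- array(0, c(length(kept), nc, nt))
  for (j in seq_along(kept)) {
    idx <- onset[kept[j]] + rel
    data[j, , ] <- t(recording$data[idx, , drop = FALSE])
  }
  cond <- if (!is.null(events$condition)) events$condition[kept]
          else rep(NA_character_, length(kept))
  structure(list(
    data = data, fs = fs, t0_s = t0_s, t1_s = t1_s,
    times_s = (rel) / fs,
    conditions = cond,
    events = events[kept, , drop = FALSE],
    skipped = events[!ok, , drop = FALSE],
    baseline_window_s = NULL
  ), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d epoch(s) x %d channel(s) x %d samples @ %g Hz, t in [%g, %g) s\n",
              d[1], d[2], d[3], x$fs, x$t0_s, x$t1_s))
  if (!all(is.na(x$conditions))) {
    tab <- table(x$conditions, useNA = "no")
    cat("  conditions:", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  }
  if (!is.null(x$baseline_window_s))
    cat(sprintf("  baseline-corrected over [%g, %g] s\n",
                x$baseline_window_s[1], x$baseline_window_s[2]))
  if (nrow(x$skipped) > 0) cat(sprintf("  %d event(s) skipped (near edges)\n", nrow(x$skipped)))
  invisible(x)
}

#' Baseline-correct epochs
#'
#' Per epoch and channel, subtracts the mean over the baseline window
#' (default -750 to 0 ms, i.e. the pre-stimulus stretch).
#'
#' @param epochs An `epoch_set`.
#' @param window_s Baseline window `(start, end)` in seconds.
#' @return The corrected `epoch_set` (with `baseline_window_s` recorded).
#' @export
baseline_correct <- function(epochs, window_s = c(-0.750, 0)) {
  stopifnot(inherits(epochs, "epoch_set"))
  ## half-open [start, end), consistent with the epoch window convention:
  ## a window ending at 0 is purely pre-stimulus
  sel <- epochs$times_s >= window_s[1] & epochs$times_s < window_s[2]
  if (!any(sel))
    so_stop("parameter", "baseline window lies outside the epoch")
  d <- dim(epochs$data)
  for (e in seq_len(d[1])) {
    bl <- apply(epochs$data[e, , sel, drop = FALSE], 2, mean)  # per channel
    epochs$data[e, , ] <- epochs$data[e, , ] - bl
  }
  epochs$baseline_window_s <- window_s
  epochs
}

#' Event-related potential with standard error
#'
#' Zero-phase low-passes every epoch (default 35 Hz) and averages over
#' epochs; the across-epoch standard error is returned for error shading.
#'
#' @param epochs An `epoch_set` with at least one epoch.
#' @param lowpass_hz Low-pass corner frequency in Hz; `NULL` skips filtering.
#' @param order Butterworth order (applied forward and backward).
#' @return Object of class `so_erp`: `mean` and `se` are channels x time
#'   matrices; `times_s`, `fs`, `n_epochs` describe them.
#' @export
erp <- function(epochs, lowpass_hz = 35, order = 4) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  if (d[1] < 1) so_stop("insufficient_data", "no epochs to average")
  x <- epochs$data
  if (!is.null(lowpass_hz)) {
    filt <- signal::butter(order, lowpass_hz / (epochs$fs / 2), type = "low")
    for (e in seq_len(d[1])) for (ch in seq_len(d[2]))
      x[e, ch, ] <- filt_zerophase(filt, x[e, ch, ])
  }
  m <- apply(x, c(2, 3), mean)
  se <- if (d[1] > 1) apply(x, c(2, 3), sd) / sqrt(d[1])
        else matrix(NA_real_, d[2], d[3])
  structure(list(mean = m, se = se, times_s = epochs$times_s,
                 fs = epochs$fs, n_epochs = d[1]),
            class = "so_erp")
}

#' @export
print.so_erp <- function(x, ...) {
  cat(sprintf("<so_erp> %d channel(s) x %d samples, average of %d epoch(s)\n",
              nrow(x$mean), ncol(x$mean), x$n_epochs))
  invisible(x)
}

#' Plot an ERP with standard-error shading
#'
#' @param x An `so_erp`.
#' @param channel Channel index.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.so_erp <- function(x, channel = 1, ...) {
  m <- x$mean[channel, ]; s <- x$se[channel, ]
  graphics::plot(x$times_s, m, type = "n", xlab = "time (s)",
                 ylab = "amplitude", ...)
  if (!all(is.na(s)))
    graphics::polygon(c(x$times_s, rev(x$times_s)),
                      c(m + s, rev(m - s)), border = NA,
                      col = grDevices::adjustcolor("steelblue", 0.3))
  graphics::lines(x$times_s, m, col = "steelblue4")
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Phase-matched fake events preceding each stimulus
#'
#' For every stimulus, searches the phase trace over the preceding
#' `lookback_s` seconds for the latest sample at which the phase rises
#' through the stimulus phase (circular crossing, within `tolerance_deg`),
#' and labels it as a fake event (`fake_up` for up-condition stimuli,
#' `fake_down` for down). Fake events thus share the stimulus' SO phase but
#' carry no stimulation, isolating stimulus-evoked from spontaneous
#' SO-locked activity. Stimuli with no qualifying crossing are reported in
#' `$unmatched` — never fabricated.
#'
#' @param stim_events Event table (`sample`, `condition` in
#'   `c("up", "down")`).
#' @param phase_trace Per-sample phase in degrees (e.g. [offline_phase()]).
#' @param fs Sampling rate, Hz.
#' @param lookback_s Search window before each stimulus, seconds.
#' @param tolerance_deg Maximum circular distance between the crossing
#'   sample's phase and the stimulus phase.
#' @param marker_offset_s Offset applied when reading the stimulus phase
#'   (and subtracted back from the matched sample), so that matching is
#'   done at the stimulus midpoint; default 0 matches at the event sample.
#' @return List with `events` (fake-event table, columns `sample`, `label`,
#'   `condition`, `stim_sample`, `phase_deg`) and `unmatched` (stimuli
#'   without a match).
#' @export
match_fake_events <- function(stim_events, phase_trace, fs, lookback_s = 3.0,
                              tolerance_deg = 2, marker_offset_s = 0) {
  off <- round(marker_offset_s * fs)
  look <- round(lookback_s * fs)
  n <- length(phase_trace)
  res <- vector("list", nrow(stim_events))
  matched <- logical(nrow(stim_events))
  for (j in seq_len(nrow(stim_events))) {
    s <- stim_events$sample[j] + off
    if (s < 1 || s > n) next
    phi <- phase_trace[s]
    i0 <- max(2L, s - look)
    i1 <- s - 1L
    if (i1 < i0) next
    idx <- i0:i1
    ## rising crossing of phi between samples i-1 and i:
    ## phase[i-1] below phi and phase[i] at/above it (circularly), moving
    ## forward by less than half a turn
    d_prev <- wrap180(phi - phase_trace[idx - 1L])
    d_curr <- wrap180(phase_trace[idx] - phi)
    step <- wrap180(phase_trace[idx] - phase_trace[idx - 1L])
    cross <- d_prev > 0 & d_curr >= 0 & step > 0 & d_prev <= 180 &
      circ_dist_deg(phase_trace[idx], phi) <= tolerance_deg
    if (any(cross)) {
      i_match <- idx[max(which(cross))]
      matched[j] <- TRUE
      res[[j]] <- data.frame(
        sample = i_match - off,
        label = "fake",
        condition = paste0("fake_", stim_events$condition[j]),
        stim_sample = stim_events$sample[j],
        phase_deg = phase_trace[i_match],
        stringsAsFactors = FALSE)
    }
  }
  list(events = if (any(matched)) do.call(rbind, res[matched]) else
         cbind(empty_event_table(),
               data.frame(stim_sample = integer(0), phase_deg = numeric(0))),
       unmatched = stim_events[!matched, , drop = FALSE])
}
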