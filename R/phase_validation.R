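# Offline phase extraction, circular statistics, and the subject-inclusion
# criteria used to judge phase-targeting performance.

#' Offline instantaneous SO phase (filter-Hilbert)
#'
#' Zero-phase Butterworth band-pass at 0.5-1.5 Hz, Hilbert analytic angle,
#' shifted by +90 degrees to the sine convention (90 deg at band-passed
#' signal peaks, 270 deg at troughs) and wrapped to \[0, 360).
#'
#' @param x Numeric signal (single channel).
#' @param fs Sampling rate, Hz.
#' @param band Pass band in Hz, default `c(0.5, 1.5)`.
#' @param order Butterworth order (applied forward and backward).
#' @return Per-sample phase in degrees.
#' @export
offline_phase <- function(x, fs, band = c(0.5, 1.5), order = 2) {
  if (length(x) <= 4 * fs)
    so_stop("parameter", "signal shorter than 4 s: band-pass unstable")
  filt <- bandpass_butter(order, band[1], band[2], fs)
  y <- filt_zerophase(filt, x)
  wrap360(rad2deg(Arg(analytic_signal(y))) + 90)
}

#' Phase at (offset) event samples
#'
#' Reads a phase trace at `sample + round(marker_offset_s * fs)` for every
#' event; the default offset of 0.25 s points at the midpoint of a 500 ms
#' stimulus whose playback started at the trigger. Out-of-bounds events are
#' reported, not silently dropped.
#'
#' @param phase_trace Per-sample phase in degrees.
#' @param events Event table (data frame with a `sample` column).
#' @param fs Sampling rate, Hz.
#' @param marker_offset_s Offset added to every event, seconds.
#' @return List with `angles_deg` (one per in-bounds event) and `skipped`
#'   (data frame of out-of-bounds events).
#' @export
phase_at_events <- function(phase_trace, events, fs, marker_offset_s = 0.250) {
  idx <- events$sample + round(marker_offset_s * fs)
  ok <- idx >= 1 & idx <= length(phase_trace)
  list(angles_deg = phase_trace[idx[ok]],
       skipped = events[!ok, , drop = FALSE])
}

#' Circular mean, resultant length and circular SD
#'
#' Vector-average definition: the mean direction and length of the mean
#' resultant vector; the circular SD is `sqrt(-2 log R)` (in degrees).
#' For `R = 0` (perfectly balanced angles) the mean is undefined and
#' returned as `NA` with `mean_defined = FALSE`.
#'
#' @param angles_deg Angles in degrees.
#' @return List of class `circ_summary` with `n`, `mean_deg`,
#'   `resultant_R`, `circ_sd_deg`, `mean_defined`.
#' @export
circ_mean_resultant <- function(angles_deg) {
  n <- length(angles_deg)
  if (n < 1) so_stop("insufficient_data", "no angles supplied")
  a <- deg2rad(angles_deg)
  C <- mean(cos(a)); S <- mean(sin(a))
  R <- sqrt(C^2 + S^2)
  defined <- R > .Machine$double.eps^0.5
  structure(list(
    n = n,
    mean_deg = if (defined) wrap360(rad2deg(atan2(S, C))) else NA_real_,
    resultant_R = R,
    circ_sd_deg = if (R > 0) rad2deg(sqrt(-2 * log(R))) else Inf,
    mean_defined = defined
  ), class = "circ_summary")
}

#' @export
print.circ_summary <- function(x, ...) {
  cat(sprintf("<circ_summary> n = %d, mean = %s deg, R = %.4f, circ SD = %.1f deg\n",
              x$n, if (x$mean_defined) sprintf("%.1f", x$mean_deg) else "undefined",
              x$resultant_R, x$circ_sd_deg))
  if (!is.null(x$rayleigh_Z))
    cat(sprintf("  Rayleigh Z = %.2f, p = %.3g\n", x$rayleigh_Z, x$rayleigh_p))
  invisible(x)
}

#' Rayleigh test of circular uniformity
#'
#' Statistic `Z = n * R^2`; the p-value uses the standard small-sample
#' corrected approximation
#' `p = exp(sqrt(1 + 4n + 4(n^2 - Rn^2)) - (1 + 2n))` with `Rn = n * R`.
#'
#' @param angles_deg Angles in degrees (n >= 2).
#' @return List with `Z`, `p`, `n`, `R`.
#' @export
rayleigh_test <- function(angles_deg) {
  n <- length(angles_deg)
  if (n < 2) so_stop("insufficient_data", "Rayleigh test needs n >= 2")
  cs <- circ_mean_resultant(angles_deg)
  Rn <- n * cs$resultant_R
  Z <- Rn^2 / n                          # = n * R^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - Rn^2)) - (1 + 2 * n))
  list(Z = Z, p = min(1, p), n = n, R = cs$resultant_R)
}

## kappa estimate from a mean resultant length (ML approximation).
kappa_from_R <- function(r) {
  if (r < 0.53) 2 * r + r^3 + 5 * r^5 / 6
  else if (r < 0.85) -0.4 + 1.39 * r + 0.43 / (1 - r)
  else 1 / (r^3 - 4 * r^2 + 3 * r)
}

#' Watson-Williams test for equal mean directions
#'
#' One-way circular ANOVA: with per-group resultant lengths \eqn{R_i}
#' (vector norms) and pooled resultant \eqn{R},
#' \eqn{F = K (N - k)(\sum R_i - R) / ((k - 1)(N - \sum R_i))},
#' where the correction factor \eqn{K = 1 + 3/(8\hat\kappa)} uses the
#' concentration estimated from the within-group resultant. A warning is
#' issued when the concentration is too low for the test's assumptions
#' (within-group mean resultant length < 0.45).
#'
#' @param ... Two or more numeric vectors of angles in degrees, or a single
#'   list of such vectors.
#' @return List with `F`, `p`, `df1`, `df2`, `kappa`.
#' @export
watson_williams_test <- function(...) {
  groups <- list(...)
  if (length(groups) == 1 && is.list(groups[[1]])) groups <- groups[[1]]
  k <- length(groups)
  if (k < 2) so_stop("parameter", "need at least two groups")
  ns <- vapply(groups, length, 0L)
  if (any(ns < 2)) so_stop("insufficient_data", "each group needs n >= 2")
  N <- sum(ns)
  Ri <- vapply(groups, function(g) {
    a <- deg2rad(g); sqrt(sum(cos(a))^2 + sum(sin(a))^2)
  }, 0)
  all_a <- deg2rad(unlist(groups))
  R <- sqrt(sum(cos(all_a))^2 + sum(sin(all_a))^2)
  rw <- sum(Ri) / N                      # within-group mean resultant length
  if (rw < 0.45)
    warning("Watson-Williams test: within-group concentration low (r < 0.45); ",
            "the F approximation may be unreliable")
  kap <- kappa_from_R(rw)
  K <- 1 + 3 / (8 * kap)
  Fstat <- K * ((N - k) * (sum(Ri) - R)) / ((k - 1) * (N - sum(Ri)))
  Fstat <- max(0, Fstat)
  list(F = Fstat, p = pf(Fstat, k - 1, N - k, lower.tail = FALSE),
       df1 = k - 1, df2 = N - k, kappa = kap)
}

#' Subject-inclusion check for phase-targeting performance
#'
#' A subject's targeting run is included when all three criteria hold:
#' the circular distance of the mean up-targeted phase from the up state
#' (90 deg) is below 45 deg; the up-targeted distribution is significantly
#' non-uniform (Rayleigh p < 0.05); and the up- and down-targeted
#' distributions differ (Watson-Williams p < 0.05). Down-targeted angles
#' are deliberately not required to lie near the down state (270 deg) or to
#' be non-uniform: down-state prediction is harder, and distinctness of the
#' two distributions is what the contrast needs.
#'
#' @param up_angles_deg Achieved phases of up-targeted stimuli, degrees.
#' @param down_angles_deg Achieved phases of down-targeted stimuli, degrees.
#' @param max_deviation_deg Inclusion bound on the up-mean deviation.
#' @param alpha Significance level for both tests.
#' @return Object of class `inclusion_report`.
#' @export
inclusion_check <- function(up_angles_deg, down_angles_deg,
                            max_deviation_deg = 45, alpha = 0.05) {
  if (length(up_angles_deg) < 1 || length(down_angles_deg) < 1)
    so_stop("insufficient_data", "both angle lists must be non-empty")
  up <- circ_mean_resultant(up_angles_deg)
  dev <- if (up$mean_defined) circ_dist_deg(up$mean_deg, 90) else Inf
  ray <- rayleigh_test(up_angles_deg)
  ww <- watson_williams_test(up_angles_deg, down_angles_deg)
  structure(list(
    mean_up_deviation_deg = dev,
    up_mean_deg = up$mean_deg,
    up_rayleigh_Z = ray$Z, up_rayleigh_p = ray$p,
    ww_F = ww$F, ww_p = ww$p,
    n_up = length(up_angles_deg), n_down = length(down_angles_deg),
    included = (dev < max_deviation_deg) && (ray$p < alpha) && (ww$p < alpha)
  ), class = "inclusion_report")
}

#' @export
print.inclusion_report <- function(x, ...) {
  cat("<inclusion_report>\n")
  cat(sprintf("  up mean %.1f deg (deviation from 90: %.1f deg; bound 45)\n",
              x$up_mean_deg, x$mean_up_deviation_deg))
  cat(sprintf("  up Rayleigh Z = %.2f, p = %.3g (n = %d)\n",
              x$up_rayleigh_Z, x$up_rayleigh_p, x$n_up))
  cat(sprintf("  Watson-Williams F = %.2f, p = %.3g (n down = %d)\n",
              x$ww_F, x$ww_p, x$n_down))
  cat(sprintf("  included: %s\n", if (x$included) "yes" else "no"))
  invisible(x)
}

#' Full circular summary for a condition
#'
#' Convenience wrapper combining [circ_mean_resultant()] and
#' [rayleigh_test()].
#'
#' @param angles_deg Angles in degrees.
#' @return `circ_summary` augmented with `rayleigh_Z` and `rayleigh_p`.
#' @export
circ_summary <- function(angles_deg) {
  cs <- circ_mean_resultant(angles_deg)
  if (cs$n >= 2) {
    r <- rayleigh_test(angles_deg)
    cs$rayleigh_Z <- r$Z
    cs$rayleigh_p <- r$p
  }
  cs
}
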