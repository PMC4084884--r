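# Streaming phase predictor: spectral estimation, online phase, sine
# fitting, lead compensation, target-time prediction, and the state
# machine's criteria and contracts.

cfg <- predictor_config()

test_that("centre frequency is the FFT argmax bin inside the search band", {
  ## single tones land on the nearest bin (spacing fs/buffer_len = 0.1024 Hz)
  expect_equal(estimate_center_frequency(sine_buffer(1.0), cfg), 1.0240)
  expect_equal(estimate_center_frequency(sine_buffer(0.8), cfg), 0.8192)
  ## tone + white noise: oracle = dense periodogram argmax over the band
  set.seed(11)
  noisy <- sine_buffer(0.7) + rnorm(cfg$buffer_len, sd = 0.3)
  est <- estimate_center_frequency(noisy, cfg)
  dense_f <- seq(0.6, 1.2, by = 1e-4)
  t <- (seq_len(cfg$buffer_len) - 1) / cfg$fs
  pg <- vapply(dense_f, function(f) Mod(sum(noisy * exp(-2i * pi * f * t)))^2, 0)
  expect_lt(abs(est - dense_f[which.max(pg)]), cfg$fs / cfg$buffer_len)
  expect_equal(est, 0.7168)   # bin k = 7
  ## short buffers are a not-ready condition
  expect_error(estimate_center_frequency(numeric(100), cfg),
               class = "sophase_not_ready")
})

test_that("SO-band power ratio matches analytic expectations", {
  ## an in-band tone carries essentially all power (exact on a bin; slightly
  ## less off-bin because rectangular-window leakage spills out of the band)
  expect_gt(so_power_ratio(sine_buffer(1.024), cfg), 0.99)
  expect_gt(so_power_ratio(sine_buffer(1.0), cfg), 0.9)
  ## broadband white noise: expected flat-spectrum fraction = band/Nyquist
  set.seed(3)
  ratios <- replicate(10, so_power_ratio(rnorm(cfg$buffer_len), cfg))
  expect_lt(mean(ratios), 0.01)
  expect_equal(mean(ratios), 0.6 / 256, tolerance = 0.5)  # ~0.0023
  ## sine plus equal-power white noise splits power ~50/50
  set.seed(4)
  amp <- 1
  noise <- rnorm(cfg$buffer_len, sd = amp / sqrt(2))   # power amp^2/2 each
  expect_equal(so_power_ratio(sine_buffer(1.0) * amp + noise, cfg), 0.5,
               tolerance = 0.05)
  expect_error(so_power_ratio(numeric(cfg$buffer_len), cfg),
               class = "sophase_undefined_ratio")
})

test_that("online instantaneous phase follows the sine convention and flags DC", {
  buf <- sine_buffer(1.024)
  ## lag-corrected phase tracks the true phase 360 f t to within 10 degrees
  ## inside the fit window (oracle: analytic phase of the known sinusoid)
  ph_corr <- instantaneous_phase(buf, 1.024, cfg, correct_lag = TRUE)
  idx <- 4000:4750
  t <- (idx - 1) / cfg$fs
  expect_lt(max(circ_dist_t(ph_corr[idx], (360 * 1.024 * t) %% 360)), 10)
  ## convention check: the uncorrected phase is 90 deg (+-2) at band-passed
  ## local maxima inside the fit window
  ph <- instantaneous_phase(buf, 1.024, cfg)
  filt <- signal::butter(1, c(1.024 - 0.5, 1.024 + 0.5) / 256, "pass")
  bp <- as.numeric(signal::filter(filt, buf))
  pk <- which(diff(sign(diff(bp))) == -2) + 1
  pk_all <- pk[pk >= 4000 & pk <= 4750]
  expect_gt(length(pk_all), 0)
  expect_lt(max(circ_dist_t(ph[pk_all], 90)), 5)
  ## away from the buffer end (analytic-signal end effects) the convention
  ## is tight
  pk_core <- pk[pk >= 4000 & pk <= 4500]
  expect_gt(length(pk_core), 0)
  expect_lt(max(circ_dist_t(ph[pk_core], 90)), 2)
  expect_error(instantaneous_phase(rep(1, cfg$buffer_len), 1.0, cfg),
               class = "sophase_undefined_phase")
  expect_error(instantaneous_phase(buf, 2.0, cfg), class = "sophase_parameter")
})

test_that("sine fitting recovers phase, rejects noise, and flags short windows", {
  f0 <- 1.024
  t <- (seq_len(cfg$buffer_len) - 1) / cfg$fs
  ## self-fit of an exact phase ramp: error ~ 0, phase within 2 deg of truth
  for (phi0 in c(0, 120, 240)) {
    trace <- (360 * f0 * t + phi0) %% 360
    fit <- fit_reference_sine(trace, f0, cfg)
    expect_lt(fit$fit_error, 1e-4)
    truth_now <- (360 * f0 * t[cfg$buffer_len] + phi0) %% 360
    expect_lt(circ_dist_t(fit$fitted_phase_deg, truth_now), 2)
    ## brute-force phase grid oracle: scan offsets for the smallest MSE
    idx <- 4000:4750
    y <- sin(deg2rad_t(trace[idx]))
    grid <- seq(0, 359.5, by = 0.5)
    mse <- vapply(grid, function(g)
      mean((y - sin(2 * pi * f0 * t[idx] + deg2rad_t(g)))^2), 0)
    best <- grid[which.min(mse)]
    got_offset <- (fit$fitted_phase_deg - 360 * f0 * t[cfg$buffer_len]) %% 360
    expect_lt(circ_dist_t(got_offset, best), 1)
  }
  ## heavy phase noise: uniform +-90 deg jitter must exceed the 0.1 criterion
  set.seed(9)
  noisy_trace <- (360 * f0 * t + runif(cfg$buffer_len, -90, 90)) %% 360
  expect_gt(fit_reference_sine(noisy_trace, f0, cfg)$fit_error, 0.1)
  ## direct-MSE oracle for the reported error
  fitn <- fit_reference_sine(noisy_trace, f0, cfg)
  idx <- 4000:4750
  direct <- mean((sin(deg2rad_t(noisy_trace[idx])) -
                    sin(2 * pi * f0 * t[idx] +
                          deg2rad_t((fitn$fitted_phase_deg -
                                       360 * f0 * t[cfg$buffer_len]) %% 360)))^2)
  expect_equal(fitn$fit_error, direct, tolerance = 1e-10)
  ## a fit window shorter than one SO cycle is degenerate
  expect_error(fit_reference_sine((360 * 0.62 * t) %% 360, 0.62, cfg),
               class = "sophase_degenerate_fit")
})

test_that("lead compensation shifts the target by 360 * f0 * lead", {
  expect_equal(compensate_lead(90, 1.0, 0.25), 0)
  expect_equal(compensate_lead(90, 0.8, 0.25), 18)
  expect_equal(compensate_lead(270, 1.1, 0), 270)
  expect_error(compensate_lead(90, 1, -0.1), class = "sophase_parameter")
})

test_that("target-time prediction picks the earliest in-horizon target", {
  mkfit <- function(phase, f0) structure(
    list(center_freq_hz = f0, fitted_phase_deg = phase, fit_error = 0,
         power_ratio = 1), class = "sine_fit")
  ## linear phase advance: 10 deg at 1 Hz = 27.8 ms
  p <- predict_target_time(mkfit(350, 1.0), 0, 10000L, cfg)
  expect_equal(p$dt_s, 10 / 360, tolerance = 1e-12)
  expect_equal(p$trigger_sample, 10000L + round(10 / 360 * 512))
  ## both targets beyond the horizon: no prediction
  expect_null(predict_target_time(mkfit(0, 1.0), c(0, 180), 10000L, cfg))
  ## 0.8 Hz example: 78 deg to go = 270.8 ms > horizon; from 330 deg it fits
  expect_null(predict_target_time(mkfit(300, 0.8), c(18, 198), 10000L, cfg))
  p2 <- predict_target_time(mkfit(330, 0.8), c(18, 198), 10000L, cfg)
  expect_equal(p2$dt_s, 48 / (360 * 0.8), tolerance = 1e-12)
  expect_equal(p2$target_index, 1L)
  ## brute-force scan oracle for the chosen arrival time
  scan_dt <- (0:10000) / 1e4 * 0.5
  reached <- (330 + 360 * 0.8 * scan_dt) %% 360
  first_hit <- scan_dt[min(which(circ_dist_t(reached, 18) < 0.05))]
  expect_equal(p2$dt_s, first_hit, tolerance = 5e-3)
  expect_error(predict_target_time(mkfit(0, 1), numeric(0), 1L, cfg),
               class = "sophase_parameter")
})

test_that("white noise yields no triggers (power criterion)", {
  set.seed(42)
  trig <- run_stream(rnorm(30 * 512), cfg)
  expect_equal(nrow(trig), 0)
})

test_that("streaming contracts hold on a noiseless SO recording", {
  syn <- generate_recording(pure_sine_spec(duration_s = 120))
  trig <- run_stream(syn$recording, cfg)
  ## counting bound: at least one trigger, at most duration/timeout + 1
  expect_gte(nrow(trig), 1)
  expect_lte(nrow(trig), floor(120 * 512 / cfg$timeout_samples) + 1)
  ## time-out: inter-trigger intervals always >= 10000 samples
  if (nrow(trig) > 1) expect_true(all(diff(trig$sample) >= cfg$timeout_samples))
  ## horizon: emission at most 250 ms after the decision
  expect_true(all(trig$sample - trig$decision_sample <=
                    cfg$horizon_max_s * cfg$fs))
  ## determinism: identical replays give identical events
  expect_identical(trig, run_stream(syn$recording, cfg))
  ## empty input gives an empty trigger table
  expect_equal(nrow(run_stream(numeric(0), cfg)), 0)
})

test_that("achieved phases on a synthetic recording are close to the targets", {
  syn <- generate_recording(synth_spec(duration_s = 180, seed = 1))
  trig <- run_stream(syn$recording, cfg)
  expect_gt(nrow(trig), 3)
  ## achieved phase = ground truth at trigger + playback lead
  ach <- syn$truth$phase_deg[trig$sample + round(cfg$playback_lead_s * cfg$fs)]
  up <- ach[trig$targeted_phase_deg == 90]
  expect_gt(length(up), 1)
  expect_lt(circ_dist_t(circ_mean_t(up), 90), 45)
  ## no trigger may fire while the power criterion fails: re-evaluate the
  ## ratio on the decision-time buffer
  for (k in seq_len(nrow(trig))) {
    dec <- trig$decision_sample[k]
    buf <- syn$recording$data[(dec - cfg$buffer_len + 1):dec, 1]
    expect_gte(so_power_ratio(buf, cfg), cfg$power_ratio_min)
  }
})

test_that("multi-channel streams require a channel selector", {
  syn <- generate_recording(synth_spec(duration_s = 15, seed = 2, n_channels = 2))
  expect_error(run_stream(syn$recording, cfg), class = "sophase_parameter")
})

test_that("online phase tracking degrades as troughs sharpen", {
  ## a sharpened trough pushes harmonic distortion through the shallow
  ## order-1 band-pass, so the online phase wobbles more around the cycle
  err_for <- function(tau) {
    syn <- generate_recording(synth_spec(duration_s = 30, noise_amplitude = 0,
                                         so_freq_walk_sd = 0,
                                         so_freq_range = c(1, 1),
                                         trough_sharpening = tau,
                                         spindle_rate = 0, seed = 3))
    x <- syn$recording$data[, 1]
    be <- length(x)
    ph <- instantaneous_phase(x[(be - 4999):be], 1.024, cfg)
    idx <- 4000:4750
    mean(circ_dist_t(ph[idx], syn$truth$phase_deg[(be - 5000) + idx]))
  }
  e1 <- err_for(1); e25 <- err_for(2.5)
  expect_gt(e25, e1)
})
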