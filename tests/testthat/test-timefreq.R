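# Morlet wavelet family, its printed precision figures, decomposition,
# and dB baseline normalisation.

test_that("the wavelet family has the documented structure", {
  spec <- morlet_spec()
  expect_length(spec$freqs_hz, 35)
  expect_equal(spec$freqs_hz[1], 5)
  expect_equal(spec$freqs_hz[35], 100)
  expect_equal(spec$cycles[1], 4)
  expect_equal(spec$cycles[35], 12)
  expect_true(all(diff(spec$freqs_hz) > 0))
  expect_true(all(diff(spec$cycles) > 0))
  ## sigma = lambda / (2 pi f) to machine precision
  expect_equal(spec$sigma_s, spec$cycles / (2 * pi * spec$freqs_hz),
               tolerance = 1e-15)
  expect_equal(spec$sigma_s[1], 4 / (2 * pi * 5), tolerance = 1e-15)
  ## kernels are unit-energy
  fam <- build_wavelet_family(spec, 512)
  expect_length(fam, 35)
  for (k in fam) expect_equal(sum(Mod(k)^2), 1, tolerance = 1e-10)
  expect_error(build_wavelet_family(spec, 150), class = "sophase_aliasing")
})

test_that("wavelet precisions reproduce the published figures and scale with cycles", {
  pr <- wavelet_precisions(morlet_spec())
  expect_equal(round(1000 * pr$temporal_precision_s[1]), 255)
  expect_equal(round(1000 * pr$temporal_precision_s[35]), 38)
  expect_equal(round(pr$spectral_precision_hz[1], 1), 2.5)
  expect_equal(round(pr$spectral_precision_hz[35], 1), 16.7)
  ## doubling lambda at fixed f doubles 2 sigma and halves 1/(pi sigma)
  a <- wavelet_precisions(morlet_spec(n_freqs = 3, cycle_range = c(4, 8)))
  b <- wavelet_precisions(morlet_spec(n_freqs = 3, cycle_range = c(8, 16)))
  expect_equal(b$temporal_precision_s[1], 2 * a$temporal_precision_s[1])
  expect_equal(b$spectral_precision_hz[1], a$spectral_precision_hz[1] / 2)
})

make_epochs <- function(x, fs = 512, n_rep = 1, cond = "up") {
  n <- length(x)
  rec <- new_recording(rep(x, n_rep), fs)
  ev <- data.frame(sample = as.integer((0:(n_rep - 1)) * n + n %/% 3),
                   label = "s", condition = cond)
  ev$sample <- pmax(ev$sample, 1L)
  epoch_recording(rec, ev, t0_s = -0.5, t1_s = (n - n %/% 3 - 1) / fs)
}

test_that("decomposition localises a pure tone at the right frequency", {
  fs <- 512
  t <- seq(0, 6 - 1 / fs, by = 1 / fs)
  ep <- make_epochs(sin(2 * pi * 10 * t), fs)
  spec <- morlet_spec()
  tfr <- tf_decompose(ep, spec)
  prof <- apply(tfr$power[1, 1, , ], 1, mean)
  i_best <- which.min(abs(spec$freqs_hz - 10))
  expect_equal(which.max(prof), i_best)
  ## >= 3x any bin farther than one spectral precision from 10 Hz
  bw <- 1 / (pi * spec$sigma_s[i_best])
  far <- abs(spec$freqs_hz - 10) > bw
  expect_gt(prof[i_best], 3 * max(prof[far]))
  ## all-zero epochs give zero power; amplitude a scales power by a^2
  ep0 <- make_epochs(numeric(length(t)), fs)
  expect_true(all(tf_decompose(ep0, spec)$power == 0))
  tfr3 <- tf_decompose(make_epochs(3 * sin(2 * pi * 10 * t), fs), spec)
  expect_equal(tfr3$power, 9 * tfr$power, tolerance = 1e-8)
  ## output time axis is at the decimated rate
  expect_equal(tfr$fs_out, 100)
  expect_equal(diff(tfr$times_s)[1], 0.01)
})

test_that("white-noise power is flat across the unit-energy family", {
  fs <- 512
  set.seed(10)
  ## average over epochs of white noise: per-frequency mean power should be
  ## near-constant for L2-normalised kernels
  n <- 4 * fs
  rec <- new_recording(rnorm(20 * n), fs)
  ev <- data.frame(sample = as.integer(seq(n, 19 * n, by = n)), label = "s",
                   condition = "up")
  ep <- epoch_recording(rec, ev, t0_s = -0.5, t1_s = 2.5)
  spec <- morlet_spec(n_freqs = 10)
  tfr <- tf_decompose(ep, spec)
  core <- tfr$times_s > 0 & tfr$times_s < 2     # avoid convolution edges
  prof <- apply(tfr$power[, , , core], 3, mean)
  expect_lt(max(prof) / min(prof), 2)
})

test_that("dB normalisation is exact on constructed power fields", {
  fs <- 512
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  set.seed(2)
  ep <- make_epochs(rnorm(length(t)), fs, n_rep = 6)
  tfr <- tf_decompose(ep, morlet_spec(n_freqs = 8))
  sel <- tfr$times_s >= -0.2 & tfr$times_s < 0
  ## power identical to its baseline mean throughout the baseline window
  ## normalises to exactly 0 dB there (dB of a ratio of 1)
  tfr_flat <- tfr
  blp0 <- apply(tfr$power[, , , sel, drop = FALSE], c(2, 3), mean)
  d <- dim(tfr$power)
  for (e in seq_len(d[1]))
    for (ti in which(sel)) tfr_flat$power[e, , , ti] <- blp0
  flat <- db_normalize(tfr_flat)
  bl_db <- apply(flat$power[, , , sel, drop = FALSE], c(2, 3), mean)
  expect_true(all(abs(bl_db) < 1e-8))
  base <- db_normalize(tfr)
  ## 10x / 100x baseline become +10 / +20 dB exactly
  tfr10 <- tfr; tfr100 <- tfr
  blp <- apply(tfr$power[, , , sel, drop = FALSE], c(2, 3), mean)
  d <- dim(tfr$power)
  for (e in seq_len(d[1])) {
    tfr10$power[e, , , ] <- array(10 * blp, d[c(2, 3, 4)])
    tfr100$power[e, , , ] <- array(100 * blp, d[c(2, 3, 4)])
  }
  ## their baselines are now 10x/100x the original, so normalise against a
  ## fixed external baseline by pooling with untouched pre-stimulus power:
  ## simplest exact check: constant field c times baseline -> 10 log10(c)
  n10 <- db_normalize(tfr10)
  expect_equal(as.numeric(n10$power), rep(0, length(n10$power)),
               tolerance = 1e-10)   # constant field: 0 dB relative to itself
  ## direct formula check against the unnormalised field
  man <- 10 * log10(tfr$power[1, 1, 1, ] / blp[1, 1])
  expect_equal(as.numeric(base$power[1, 1, 1, ]), man, tolerance = 1e-10)
  ## renormalising is refused
  expect_error(db_normalize(base), class = "sophase_renormalize")
  ## degenerate baseline is refused
  tfr0 <- tfr; tfr0$power[] <- 0
  expect_error(db_normalize(tfr0), class = "sophase_degenerate_baseline")
})

test_that("per-condition baselines are computed within condition", {
  fs <- 512
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  n <- length(t)
  rec <- new_recording(c(sin(2 * pi * 10 * t), 2 * sin(2 * pi * 10 * t),
                         sin(2 * pi * 10 * t), 2 * sin(2 * pi * 10 * t)), fs)
  ev <- data.frame(sample = as.integer(c(0, 1, 2, 3) * n + n %/% 2),
                   label = "s", condition = c("up", "down", "up", "down"))
  ep <- epoch_recording(rec, ev, t0_s = -0.5, t1_s = 1.5)
  tfr <- tf_decompose(ep, morlet_spec(n_freqs = 6))
  norm_pc <- db_normalize(tfr, mode = "per-condition")
  ## both conditions are internally stationary, so each normalises to ~0 dB
  core <- norm_pc$times_s > 0.2 & norm_pc$times_s < 1
  i10 <- which.min(abs(norm_pc$freqs_hz - 10))
  expect_lt(max(abs(norm_pc$power[, , i10, core])), 0.5)
  ## pooled baseline leaves a systematic offset between conditions
  norm_pool <- db_normalize(tfr, mode = "pooled")
  up_m <- mean(norm_pool$power[c(1, 3), , i10, core])
  down_m <- mean(norm_pool$power[c(2, 4), , i10, core])
  expect_gt(down_m - up_m, 3)    # 4x power ratio ~ 6 dB apart
})

test_that("window averages reduce the dB field over the exact box", {
  fs <- 512
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  ep <- make_epochs(sin(2 * pi * 10 * t), fs, n_rep = 2)
  tfr <- tf_decompose(ep, morlet_spec(n_freqs = 6))
  ## constant synthetic field: any window returns the constant
  tfr$power[] <- 3
  expect_equal(as.numeric(window_average(tfr, c(5, 100), c(0, 1))),
               rep(3, 2))
  ## field = 1 dB inside a box, 0 outside: exact box mean is 1
  tfr$power[] <- 0
  fsel <- tfr$freqs_hz >= 8 & tfr$freqs_hz <= 20
  tsel <- tfr$times_s >= 0.2 & tfr$times_s <= 0.6
  tfr$power[, , fsel, tsel] <- 1
  expect_equal(as.numeric(window_average(tfr, c(8, 20), c(0.2, 0.6))),
               rep(1, 2))
  ## injected burst: in-window average exceeds the complementary window
  expect_gt(window_average(tfr, c(8, 20), c(0.2, 0.6))[1, 1],
            window_average(tfr, c(8, 20), c(1, 2))[1, 1])
  expect_error(window_average(tfr, c(300, 400), c(0, 1)),
               class = "sophase_parameter")
  ## named windows of interest are available
  woi <- window_of_interest("sleep_spindle_beta")
  expect_equal(woi$freq_band, c(11, 27))
  expect_equal(woi$time_window_s, c(0.7, 1.2))
})
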