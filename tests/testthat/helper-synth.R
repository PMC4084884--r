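# Shared fixtures, all generated in code.

pure_sine_spec <- function(duration_s = 40, freq = 1.0, fs = 512, seed = 1) {
  synth_spec(duration_s = duration_s, fs = fs, noise_amplitude = 0,
             trough_sharpening = 1, so_freq_walk_sd = 0,
             so_freq_range = c(freq, freq), spindle_rate = 0, seed = seed)
}

## a full predictor buffer containing sin(2 pi f t), t starting at 0
sine_buffer <- function(freq, cfg = predictor_config(), phase0_deg = 0) {
  t <- (seq_len(cfg$buffer_len) - 1) / cfg$fs
  sin(2 * pi * freq * t + deg2rad_t(phase0_deg))
}

deg2rad_t <- function(d) d * pi / 180

circ_dist_t <- function(a, b) {
  d <- (a - b + 180) %% 360 - 180
  abs(d)
}

## circular mean of angles in degrees (independent of the package's own
## implementation: plain vector sum)
circ_mean_t <- function(deg) {
  a <- deg * pi / 180
  (atan2(mean(sin(a)), mean(cos(a))) * 180 / pi) %% 360
}
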