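---
title: "Slow-oscillation phase targeting: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slow-oscillation phase targeting: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sophase)
```

# The problem

In deep non-REM (slow-wave) sleep the EEG is dominated by the ~1 Hz slow
oscillation (SO), an alternation between a depolarised, excitable *up
state* and a hyperpolarised, nearly silent *down state*. Stimulus
processing during sleep depends on the SO phase at stimulus arrival, so
experiments probing it need closed-loop stimulation: a streaming algorithm
that predicts, from the ongoing EEG of a single channel, when a chosen
phase will next occur, and fires a trigger so that the stimulus lands
there. `sophase` implements such a predictor together with the offline
validation and analysis chain, and a synthetic slow-wave-sleep generator
that provides ground-truth phase for end-to-end testing.

Throughout the package, phase follows the sine convention: a signal
$A\sin\varphi$ has its up-state peak at $\varphi = 90^\circ$ and its
down-state trough at $\varphi = 270^\circ$.

# The streaming predictor

The predictor (see `predictor_config()`, `predictor_step()`,
`run_stream()`) maintains a rolling buffer of `buffer_len = 5000` samples
(~10 s at `fs = 512` Hz). At each new sample, when armed, it executes:

1. **Momentary SO frequency.** The FFT amplitude argmax over
   `so_search_band = 0.6–1.2 Hz`. The bin spacing is
   `fs / buffer_len = 0.1024 Hz`; the estimate is deliberately quantised to
   the bin grid, exactly as a windowed FFT provides it.
2. **Band-power criterion.** SO-band power must be at least
   `power_ratio_min = 0.6` of the total power. *Total* is defined as all
   non-DC FFT bins up to Nyquist: the DC bin reflects amplifier offset, not
   physiology, and including it would make the criterion depend on an
   arbitrary recording constant.
3. **Analytic phase.** The buffer is band-passed with a *causal* order-1
   Butterworth of 1 Hz bandwidth centred on the momentary frequency
   (forward-only: the online path cannot look ahead), the Hilbert analytic
   signal is formed, and its angle is shifted by +90° into the sine
   convention. A key property of the analytic-phase signal
   $\sin\varphi(t)$ is that its cycle-to-cycle amplitude is constant, so
   SO-to-SO amplitude variation cannot bias the subsequent fit. The
   filter's phase lag at the centre frequency (computed from its frequency
   response; an order-1 band-pass has a non-negligible lag near 1 Hz) is
   subtracted before fitting, so the fitted phase refers to the unfiltered
   signal.
4. **Sine fit.** A unit sine $\sin(2\pi f_0 t + \phi_0)$ is least-squares
   fitted to $\sin\varphi(t)$ over the `fit_window_frac = 80–95 %` stretch
   of the buffer (~1.5 s). The last 5 % are excluded because both the
   causal filter and the Hilbert transform are unreliable at the buffer
   edge. The mean squared residual must not exceed `fit_error_max = 0.1`;
   because the fit is on the unit-amplitude phase signal, this threshold is
   dimensionless and independent of signal scale.
5. **Prediction.** The fitted phase is extrapolated linearly at
   $360 f_0$ °/s. For each target the earliest future arrival of its
   *lead-compensated* phase `(target − 360·f0·playback_lead_s) mod 360` is
   computed; the earliest target overall wins, with ties broken toward the
   earlier entry of `target_phases_deg` (up before down at the defaults —
   an arbitrary but fixed rule). If even the earliest arrival exceeds
   `horizon_max_s = 250 ms`, no trigger is scheduled and the next sample is
   analysed instead: predictions further out would be based on stale
   information.
6. **Suspension and time-out.** Between a scheduled prediction and its
   emission, analysis is suspended (the decision stands). After each
   trigger a `timeout_samples = 10000` (~20 s) refractory period follows,
   giving an operator time to intervene if a stimulus caused an arousal.

The lead compensation (`compensate_lead()`) makes the *midpoint* of a
stimulus of duration `2 × playback_lead_s` coincide with the target phase;
the default 250 ms corresponds to 500 ms stimuli. Because the phase advance
is computed from the momentary frequency, a slower SO starts playback later
in phase than a faster one.

Criteria are re-evaluated at every sample while armed ("continuous"
operation); the band-power check is computed from the same FFT as the
frequency estimate, so the per-sample cost stays modest, and the expensive
filter–Hilbert–fit path only runs once the power criterion passes.

A degenerate case worth noting: if the momentary frequency estimate is so
low that the 1.46 s fit window holds less than one SO cycle
(`f0 < ~0.68 Hz`), the fit is refused (`sophase_degenerate_fit`) and the
step simply produces no prediction.

## Open design choices

* *Fit target.* Whether the reference sine should be fitted to the
  normalised phase signal $\sin\varphi(t)$ or to the raw band-passed
  signal is ambiguous; the constant-amplitude argument above favours the
  normalised form, which is the default, but
  `predictor_config(fit_raw_analytic = TRUE)` switches to a free-amplitude
  fit on the raw signal with a relative (residual/signal mean square) error
  measure.
* *Error scale.* The 0.1 fit threshold is interpreted as a *mean* (not
  summed) squared residual on the unit-amplitude signal, which makes it
  independent of the fit-window length.
* *Horizon origin.* The 250 ms horizon is measured from the newest sample
  at decision time.

# Offline validation

`offline_phase()` re-derives the phase the way an offline analysis would:
zero-phase (forward–backward) Butterworth band-pass at 0.5–1.5 Hz, Hilbert
angle, +90°. `phase_at_events()` reads this trace at trigger + 250 ms — the
stimulus midpoint. Targeting quality is then judged with circular
statistics (`circ_mean_resultant()`, `rayleigh_test()`,
`watson_williams_test()`):

* Rayleigh: $Z = nR^2$ with the standard small-sample corrected p
  approximation $p = \exp\{\sqrt{1 + 4n + 4(n^2 - R_n^2)} - (1 + 2n)\}$.
* Watson–Williams: one-way circular ANOVA with the $1 + 3/(8\hat\kappa)$
  concentration correction, $\hat\kappa$ estimated from the within-group
  mean resultant; a warning is raised when the within-group resultant falls
  below 0.45, where the F approximation becomes unreliable.

`inclusion_check()` applies the three criteria a targeting session must
meet before up/down comparisons are meaningful: mean up-targeted phase
within 45° of 90° (circular distance, i.e. the minimal absolute angular
difference), up distribution non-uniform at p < 0.05, and up vs down
distributions different at p < 0.05. Down-targeted stimuli are deliberately
*not* required to be accurate — down states are the harder target — only
distinct.

# Fake events and evoked-response analysis

To isolate stimulus-evoked activity from spontaneous SO-locked dynamics,
`match_fake_events()` finds, for every stimulus, the latest time in the
preceding 3 s at which the offline phase *rises through* the stimulus phase
(crossing detection within a 2° tolerance; the latest match keeps the
control as physiologically comparable to the stimulated wave as possible).
Stimuli without a qualifying crossing are reported as unmatched, never
fabricated. Epochs (`epoch_recording()`, −1.0 to +2.5 s, half-open
`[t0, t1)` windows so lengths are unambiguous) are baseline-corrected over
[−750, 0) ms and averaged into ERPs after a zero-phase 35 Hz low-pass.
Events within ±2 s of an arousal interval are excluded up front
(`exclude_arousal_events()`).

# Time–frequency analysis

`morlet_spec()` builds the wavelet family: 35 logarithmically spaced
frequencies on [5, 100] Hz paired *index-wise* with 35 logarithmically
spaced cycle counts $\lambda$ on [4, 12], and $\sigma = \lambda/(2\pi f)$.
The index-wise pairing is the only reading consistent with the family's
endpoint resolutions: 2σ = 255 ms and 1/(πσ) = 2.5 Hz at 5 Hz
($\lambda = 4$), 38 ms and 16.7 Hz at 100 Hz ($\lambda = 12$). Kernels are
sampled on ±4σ and L2-normalised — the support length and normalisation are
free choices; unit energy is used because it keeps white-noise power flat
across the family, and the precision figures depend only on σ. Power
(squared magnitude) and phase (angle, in (−π, π]) are extracted at the full
rate and then decimated to 100 Hz by nearest-sample selection, without an
additional anti-alias filter on the power envelopes (power time courses are
already smooth at the wavelet's own temporal scale).

`db_normalize()` divides power per channel × frequency by the mean baseline
power over [−200, 0) ms across epochs and takes $10\log_{10}$. During
sleep, pre-stimulus power differs hugely between up- and down-targeted
conditions, so the default is a *per-condition* baseline; a pooled baseline
is appropriate when pre-stimulus states are comparable (e.g. wakefulness).
Normalised TFRs carry a flag and refuse re-normalisation — dB values must
never be normalised twice. Note the exactness caveat: the *mean of dB* over
the baseline window is exactly 0 only when the baseline-window power is
stationary (dB of the mean is not the mean of dB); the package's exactness
tests therefore use baseline-stationary constructions.

# Cluster-based permutation statistics

`paired_cluster_test()` / `one_sample_cluster_test()` threshold per-point
t maps (paired t on within-subject differences, or one-sample t against 0)
at a per-point two-tailed `cluster_alpha = 0.01`, join suprathreshold
points of common sign into clusters (grid adjacency in time and frequency
plus a user-supplied, symmetrised channel-neighbour relation — channel
neighbourhoods are genuinely montage-specific, so they are an input, not a
built-in), and refer each cluster's mass (summed t) to the permutation
distribution of the per-permutation *maximum* mass of its sign
(sign-flips/condition swaps, default 1000 iterations; testing restricted to
[−200, 1500] ms). With cluster significance at 0.025 per side the
family-wise error is 0.05 two-sided. Monte-Carlo p-values use the
(+1)/(+1) correction so p = 0 cannot occur; exhaustive enumeration
(`n_permutations = "all"`) is available up to 16 subjects and then uses the
exact count without the correction. The permutation seed is a required
config field so reports are reproducible. Windows of interest used in the
analyses are shipped as named presets (`window_of_interest()`): sleep theta
5–10 Hz / 200–800 ms, sleep spindle/beta 11–27 Hz / 700–1200 ms, wake
theta 5–14 Hz / 50–300 ms, wake alpha 7–15 Hz / 500–800 ms, wake gamma
55–75 Hz / 750–1100 ms.

# The synthetic generator

`generate_recording()` emulates the signal regime the predictor assumes —
it is a test instrument, not a thalamocortical model:

* **SO component**: a frequency-modulated sinusoid whose instantaneous
  frequency performs a reflecting random walk inside 0.6–1.2 Hz
  (`so_freq_walk_sd = 0.05` Hz per cycle: slow, realistic cycle-to-cycle
  wandering), amplitude 75 (arbitrary units, think µV — typical of frontal
  SOs).
* **Waveform asymmetry**: real down states are sharper than up states. This
  is modelled by a monotone periodic phase warp
  $\psi = \varphi - c\,\sin(\varphi - 90^\circ)$, $c = 1 - 1/\tau$ with
  `trough_sharpening` $\tau = 1.5$ by default, which fixes 90° and 270° and
  makes the waveform traverse the trough $2\tau - 1$ times faster than the
  peak. Ground-truth phase is the *unwarped* $\varphi$, so peaks stay at
  90° and troughs at 270° exactly.
* **Background**: $1/f$ noise (spectrally shaped white noise, SD 20 — a
  realistic SO-to-background ratio that keeps the band-power criterion
  satisfiable in clean stretches but not trivially so).
* **Spindles**: optional Gabor bursts (11–15 Hz carrier, 0.15 s envelope
  SD, 3/min) centred on up-state peaks, emulating up-state-coupled fast
  spindles.
* **Arousals**: segments where the SO is nearly silenced and broadband
  noise is tripled — giving the power criterion something to reject and the
  exclusion logic something to exclude.
* **Channels**: extra channels are amplitude-scaled, lag-shifted copies of
  the reference plus independent noise. No realistic topography or SO
  travelling is attempted.

Everything is deterministic given `seed`.

**What passing tests do and do not show.** The generator produces
stationary statistics, perfectly known phase, and no artifacts beyond the
modelled arousals; real sleep EEG adds non-stationary SO amplitude, sleep
stage transitions, eye/muscle artifacts, and electrode drift. Tests passing
on the generator therefore demonstrate the *correctness of the machinery*
(criteria logic, phase conventions, statistics), not field performance on
patients. One concrete instance: because the asymmetry is a pure phase
warp, its first-order effect on the waveform is confined to DC and the
second harmonic, so the fundamental — which both the online predictor and
the offline filter–Hilbert phase track — is nearly unaffected, and
down-targeting accuracy does *not* measurably degrade with
`trough_sharpening` in this simulator, although online phase-tracking
error around the cycle does grow (harmonic leakage through the shallow
order-1 filter). The empirically observed extra difficulty of down-state
prediction presumably involves amplitude asymmetry and non-stationarity
that a phase warp cannot carry; reproducing it would require a richer
waveform model, which is out of scope for a test instrument.

# Numerical choices and problem sizes

* Offline band-pass: order-2 Butterworth applied forward–backward (order
  unspecified by convention; order 2 is stable at 0.5 Hz corners and
  512 Hz).
* Hilbert transform: FFT construction (zero negative frequencies, double
  positive ones).
* Degenerate inputs are classed conditions (`sophase_*` error classes), so
  callers — notably the streaming state machine — can distinguish
  "no prediction possible now" from programming errors.
* EDF I/O is a minimal 16-bit implementation (one data record per second,
  equal rates across channels) sufficient for interchange with sleep
  software; delimited text is the lossless test-suite format.
* Test problem sizes: streaming tests replay 30–300 s of 512 Hz signal;
  the statistical calibration uses 200 simulated 12-subject experiments
  with 200 permutations on a 15 × 20 time–frequency grid. These sizes give
  stable statistics (e.g. a ±3 % binomial CI on the family-wise error rate)
  while keeping the full suite around a minute of CPU.

# Known limitations

* The predictor's frequency estimate is quantised to the FFT bin grid
  (0.1024 Hz); extrapolation over the ~1.2 s from fit-window centre to
  target can accumulate a systematic phase error of ~10° when the true
  frequency falls between bins. This is inherent to the design (visible as
  the small bias in achieved phases) and is part of what the inclusion
  criteria absorb.
* Down-state targeting difficulty is not reproduced by the generator (see
  above).
* The Watson–Williams test assumes concentrated von-Mises-like samples;
  with diffuse phase distributions its F approximation is only indicative
  (a warning is raised).
* No real-time amplifier interface is included; `run_stream()` replays
  recorded or synthetic signals through the same state machine the online
  path would use.
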