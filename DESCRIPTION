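Package: sophase
Title: Real-Time Slow-Oscillation Phase Targeting and Sleep-EEG Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for delivering and analysing stimuli phase-locked to the
    ~1 Hz slow oscillation (SO) of deep non-REM sleep. Implements a streaming
    phase-prediction algorithm (FFT-based momentary SO frequency estimation,
    causal band-pass filtering, Hilbert analytic phase, least-squares sine
    fitting and extrapolation, with power, fit-quality, horizon and time-out
    criteria), offline validation via filter-Hilbert phase extraction and
    circular statistics (Rayleigh and Watson-Williams tests, subject inclusion
    criteria), phase-matched fake-event construction, epoching and
    event-related potentials, complex Morlet wavelet time-frequency analysis
    with decibel baseline normalisation, cluster-based permutation statistics,
    and a synthetic slow-wave-sleep EEG generator with ground-truth phase for
    end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
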