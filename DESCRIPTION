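Package: pulsewave
Title: Cardiac Phase-Locking of Sleep Slow Waves in EEG, ECG and NIRS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to test whether the onsets of individual sleep slow waves are
    phase-locked to the cardiac pulsation visible in frequency-domain NIRS and in
    the ECG. Implements envelope-based slow-wave detection on six-channel sleep
    EEG, trigger-based synchronization between EEG and NIRS clocks, event-locked
    evoked responses (nERP/eERP) with per-trial linear detrending, a bounded-lag
    Pearson cross-correlation against a heart-rate-matched sine template, and a
    random-latency permutation test for individual-night significance. A synthetic
    multimodal recording generator with known cardiac-to-slow-wave coupling makes
    every stage testable without clinical data.
License: MIT + file LICENSE
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
    yaml,
    car,
    withr
Config/testthat/edition: 3
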