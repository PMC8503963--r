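Package: hfotools
Title: Detection, Characterization and Simulation of High-Frequency
    Oscillations in Intracranial EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting high-frequency oscillations (HFOs) in
    intracranial EEG. Implements a two-threshold Hilbert-envelope detector
    with cycle-based event qualification, a single-threshold duration-based
    comparator detector, a continuous Gabor-wavelet spectrogram with
    click-guided narrow-band detection, event characterization (average
    frequency, cycle count, peak z-score), a synthetic iEEG simulator with
    ground-truth event insertion, and a validation harness that scores
    detectors against ground truth across noise levels. Recordings are read
    from and written to European Data Format (EDF); event lists and
    per-channel summaries use tab-separated text tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
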