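Package: neuroconn
Title: Connectivity and Phase-Amplitude Coupling Analysis for Neurophysiological Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating functional connectivity from multichannel
    neurophysiological recordings (EEG, MEG, LFP). Provides preprocessing
    (common average re-referencing, downsampling), linear-phase FIR filtering
    via FFT overlap-add with fast and precise modes, artifact handling
    (band-power bad-channel detection, neighbor-average channel restoration,
    iterative z-score outlier removal), segmented cross-spectra and complex
    coherency, same-frequency coupling metrics (magnitude squared coherence,
    imaginary coherence, weighted phase lag index, phase slope index,
    directional absolute coherency), phase-amplitude coupling metrics
    (modulation index, direct modulation index, phase-locking value, mean
    vector length), significance-aware topographic maps, chunked binary
    array storage for large recordings, and seeded synthetic-signal
    generators with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    generics,
    ggplot2,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    dplyr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
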