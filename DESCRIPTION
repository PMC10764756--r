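Package: leapd
Title: EEG-Based Cognitive Indexing via Linear Predictive Coding and
    Affine-Subspace Geometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements LEAPD, an EEG-based index of cognitive function.
    Resting-state EEG channels are encoded as linear predictive coding (LPC)
    autoregressive coefficient vectors; cognitively impaired and cognitively
    normal training groups each define an affine subspace in LPC-coefficient
    space, and a recording is scored by the normalized ratio of its distances
    to the two subspaces. Includes fixed preprocessing (energy normalization,
    FFT line-noise removal, zero-phase Butterworth bandpass), exhaustive
    per-electrode parameter search with a cross-validated Spearman-rho cost,
    electrode selection, a full evaluation harness (leave-one-out and k-fold
    cross-validation, randomization tests, age-adjusted partial Spearman
    correlation, ROC/classification and regression metrics, electrode-count
    and recording-truncation robustness sweeps), canonical spectral-power
    baselines, a synthetic EEG cohort generator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
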