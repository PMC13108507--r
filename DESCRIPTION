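Package: syncmeta
Title: Phase Synchrony and Metastability of Parcellated BOLD Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes instantaneous phase synchrony (Kuramoto order
    parameter) and metastability of resting-state functional networks from
    parcellated BOLD fMRI time series. Narrowband oscillatory components are
    extracted by empirical mode decomposition, instantaneous phase by the
    analytic signal, and per-network synchrony/metastability scalars are
    combined into a sync-metastability feature vector. Includes a split-half
    resampling engine that profiles within-subject reliability as a function
    of total acquisition duration, a static functional-connectivity
    comparator, phase-randomized surrogate nulls with effect-size statistics,
    departure-from-baseline state-change quantification, and a coupled
    phase-oscillator simulator for generating synthetic multi-session
    cohorts with known coupling structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
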