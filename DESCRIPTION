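Package: hybridbci
Title: Ternary Hybrid EEG-NIRS Brain-Computer Interface Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decoding pipeline for a ternary hybrid electroencephalography
    (EEG) and near-infrared spectroscopy (NIRS) brain-computer interface
    discriminating mental arithmetic, motor imagery, and idle state.
    Implements EEG conditioning (anti-aliased downsampling, zero-phase
    Butterworth band-pass filtering via second-order sections, regression
    based ocular-artifact removal, epoching), NIRS conditioning (modified
    Beer-Lambert conversion of optical densities to hemoglobin concentration
    changes, narrow-band filtering, baseline correction), filter-bank common
    spatial pattern features, shrinkage linear discriminant analysis with
    analytic Ledoit-Wolf/Schaefer-Strimmer regularization, one-versus-one
    decomposition with a stacked EEG+NIRS meta-classifier and majority
    voting, repeated stratified cross-validation, information-transfer-rate
    and event-related spectral perturbation metrics, and a synthetic
    multimodal session generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    signal,
    withr
Config/testthat/edition: 3
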