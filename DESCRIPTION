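Package: avTRF
Title: Temporal Response Function Encoding Models for Audiovisual EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Forward (encoding) models of continuous EEG responses to
    audiovisual stimuli. Extracts auditory features (binary phonological
    onsets, acoustic envelope, autocorrelation pitch) and visual features
    (spatiotemporal Gabor motion energy reduced to principal components,
    scene-cut impulses) at 128 Hz, fits delay-embedded ridge-regression
    temporal response functions (mTRFs) per channel with cross-validated
    regularization, assesses significance by chunk-shuffle permutation,
    and compares within- versus cross-condition prediction between
    audiovisual, audio-only and visual-only stimulation. Includes readers
    for WAV, Praat TextGrid, BrainVision and EDF, a bit-exact internal
    matrix container, and a synthetic-data generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    Matrix,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
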