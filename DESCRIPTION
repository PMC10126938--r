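Package: stlfl
Title: Spatial-Temporal Linear Feature Learning for P300 Brain-Computer Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Single-trial P300 detection and speller character decoding from
    multichannel EEG. Implements spatial-temporal linear feature learning
    (STLFL), a bilinear Fisher-type discriminant that learns a spatial and a
    temporal projection by alternating generalized eigendecompositions, and a
    hybrid discriminative restricted Boltzmann machine (DRBM) classifier over
    the projected features. Includes oddball paradigm bookkeeping for
    row-column (6x6 matrix) and rapid-serial-visual-presentation (9-group)
    spellers, a seeded synthetic session simulator with colored noise and a
    parametric event-related-potential template, band-pass/decimation
    preprocessing profiles, repetition-aggregated character decoding, and
    evaluation utilities (information transfer rate, selection time,
    point-biserial discriminability, hyperparameter search by stratified
    cross-validation).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
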