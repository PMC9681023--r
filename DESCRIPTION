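Package: imuseq
Title: Sequence-to-Sequence Decomposition and Counting of Functional
    Upper-Extremity Motion Primitives from Wearable IMU Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes multichannel inertial-measurement-unit (IMU)
    recordings of upper-extremity rehabilitation activities into ordered
    sequences of five functional primitives (reach, reposition, transport,
    stabilization, idle) using a bidirectional GRU encoder-decoder trained
    with teacher forcing and deployed as a cross-validated ensemble with
    token feedback. Includes sensor-centric quaternion preprocessing,
    z-score normalization, window/core/slide tiling of recordings, a
    boundary-deduplicating primitive counter for rehabilitation dose,
    a Levenshtein-alignment error taxonomy (deletion, swap-out, insertion,
    swap-in) with sensitivity, false discovery rate, F1 and Action Error
    Rate metrics, bootstrap model comparison, a random-forest pointwise
    baseline with Kaiser-window smoothing, and a deterministic synthetic
    kinematic data generator so the full pipeline can be trained and
    evaluated without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    ranger,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
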