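Package: synx
Title: EMG-Driven Musculoskeletal Model Calibration with Muscle Synergy
    Extrapolation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates EMG-driven Hill-type musculoskeletal models while
    simultaneously estimating unmeasured and residual muscle excitations as
    linear combinations of synergy excitations extracted from measured muscle
    excitations by principal component analysis (synergy extrapolation, SynX).
    Provides gait-cycle time normalisation, EMG processing, PCA-based muscle
    synergy analysis with trial-, speed- and subject-specific concatenation,
    a rigid-tendon Hill-type muscle model with first-order activation dynamics
    and electromechanical delay, surrogate polynomial musculoskeletal geometry,
    multi-objective joint-moment tracking calibration, validation on held-out
    trials, evaluation metrics, and a synthetic gait data generator with known
    ground truth for recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    minpack.lm,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
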