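Package: ecgpain
Title: ECG-Only Pain Recognition from Cold Pressor Protocols
Version: 0.1.0
Authors@R: person("ECG Pain", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for recognizing cold-pressor pain from a
    single-lead electrocardiogram. Provides a protocol-structured synthetic ECG
    cohort generator with analytic ground-truth fiducials, zero-phase
    Butterworth band-pass preprocessing, P/QRS/T wave delineation, windowed
    morphological feature extraction with baseline-mean normalization, three
    train/test designs (dependent, session-independent, participant-independent)
    over an eight-classifier roster, six evaluation metrics, and per-model
    feature-importance scaling for cross-model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    MASS,
    glmnet,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pheatmap,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
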