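Package: endoquant
Title: Patient-Level Endoscopy Image Classification with Abstaining
    Ensembles and Neural-Network Quantization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building patient-level classifiers from cohorts of
    endoscopic snapshots. Provides automatic image cleaning (Laplacian-variance
    quality filtering, black-margin cropping, pluggable artifact removal with
    inpainting-style fills), patient-disjoint splitting and cross-validation to
    prevent information leakage, a compact trainable convolutional backbone
    with the LASSO-regularized step-decay training recipe, a per-patient
    abstaining ensemble (confidence threshold, top-k confidence-weighted mean,
    MCC-driven grid search with evidence reporting), a from-scratch neural
    network quantization engine (post-training quantization, quantization-aware
    training with the straight-through estimator, PACT trainable clipping,
    per-tensor and per-channel granularity, model-size accounting), and
    confusion-matrix metrics with bootstrap confidence intervals. A synthetic
    cohort generator emulating endoscopy-like artifacts makes every stage
    testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
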