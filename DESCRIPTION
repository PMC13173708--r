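Package: arcdose
Title: Beam-Band Guided Dose Prediction and Auto-Planning for Arc Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, desk-scale toolkit for volumetric modulated arc
    therapy (VMAT) auto-planning research. Provides a pelvic phantom simulator
    with a parallel-ray dose engine, directional beam-band geometric priors
    built from per-slice tangent corridors around the target, a two-stage
    cascaded 3D convolutional dose-prediction model trained with a composite
    objective (body MAE, band-region MAE, gradient consistency, differentiable
    DVH agreement), a DVH-driven iterative inverse-planning loop against a
    surrogate optimizer, and a full evaluation stack (DVH endpoints, dose /
    DVH / scale-normalised DVH scores, global gamma analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
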