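Package: eventseg
Title: Brain Dynamics at Musical Event Boundaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for studying brain responses around perceived
    event boundaries in naturalistic listening fMRI. Builds a continuous
    boundary-salience regressor from real-time listener markers by kernel
    density estimation, fits lagged voxelwise general linear models with
    Fisher combined-probability pooling across subjects, performs group
    spatial independent component analysis with GICA3 back-reconstruction of
    subject-specific maps and time courses, profiles component engagement
    across pre/at/post-boundary lags, and tests directed coupling between
    component networks with a difference-of-influence Granger statistic.
    Includes permutation cluster-extent family-wise error correction, exact
    nonparametric primitives, and a synthetic 4-D data generator with planted
    spatial networks, lag structure, and causal coupling for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    lmtest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
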