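Package: boldmetrics
Title: Voxelwise Resting-State fMRI Metrics, Group Statistics and SVM Classification
Version: 0.1.0
Authors@R:
    person("BOLD", "Metrics Team", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for a multilevel resting-state fMRI analysis of two-group
    (patient versus control) BOLD cohorts: a synthetic 4D BOLD cohort generator
    with injectable group effects, the standard post-realignment preprocessing
    chain (volume discard, Friston-24 plus tissue nuisance regression, band-pass
    filtering, framewise displacement, gray-matter masking, Gaussian smoothing),
    five voxelwise local metrics (fALFF, ReHo, degree centrality, VMHC, FCS),
    seed-based functional connectivity maps, covariate-adjusted voxelwise group
    t-tests with Gaussian-random-field cluster-extent correction, ROI feature
    extraction, RBF-kernel support-vector-machine classification with nested
    cross-validation, and Shapley-value feature attribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
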