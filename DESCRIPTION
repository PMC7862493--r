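Package: kbdvh
Title: Knowledge-Based Dose-Volume Histogram Prediction for Radiotherapy
    Plans
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts organ-at-risk and planning-target-volume cumulative
    dose-volume histograms (DVHs) from per-patient geometric and dosimetric
    features, in the spirit of knowledge-based treatment planning. Two
    feature sets are provided: individual-field DVHs (IDVHs) computed from
    nine uniform-intensity conformal fields, and the distance-to-target
    histogram combined with the conformal-plan DVH (DTH + CPDVH). Curves
    are predicted with a generalized regression neural network (Gaussian
    kernel Nadaraya-Watson regression) trained separately for OARs and
    PTVs, and evaluated with the determination coefficient, mean absolute
    error, dose-volume endpoints (Dy, Vx), the uniformity index and paired
    Wilcoxon signed-rank comparisons. A seeded synthetic phantom cohort
    generator and a simplified conformal-field dose engine make the whole
    pipeline runnable and testable without clinical treatment-planning
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, Regression, StatisticalMethod
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'accessors.R'
    'dose.R'
    'histograms.R'
    'evaluation.R'
    'features.R'
    'grnn.R'
    'io.R'
    'kbdvh-package.R'
    'phantoms.R'
    'pipeline.R'
    'utils.R'
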