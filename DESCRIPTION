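Package: morphocavity
Title: Geometric Morphometrics of Nasal Cavity Morphotypes
Version: 0.1.0
Authors@R:
    person("Morphocavity", "Developers", email = "morphocavity@example.org",
           role = c("aut", "cre"))
Description: Landmark-based geometric morphometrics pipeline for discovering
    and characterizing morphotypes of the unilateral nasal cavity region of
    interest. Provides thin-plate-spline warping and bending-energy machinery,
    template-based semi-landmark transfer with tangential sliding, Generalized
    Procrustes Analysis, permutation Procrustes ANOVA, shape PCA with elbow
    selection and resampling stability, Ward clustering on principal components
    with automatic cluster-count selection, per-landmark MANOVA/ANOVA/Tukey
    characterization, Lin's concordance correlation for digitization
    repeatability, cohort demographics summaries, and a synthetic cavity-shape
    generator so the full workflow is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    cluster
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    MASS,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
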