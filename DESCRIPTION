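Package: cardiomotion
Title: Cardiorespiratory Motion Analysis of Cardiac Substructures from
    Phase-Binned Volumetric Imaging
Version: 0.1.0
Authors@R: person("cardiomotion", "developers",
    email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to decouple and quantify cardiac, respiratory, and
    hysteresis motion of cardiac substructures from phase-binned
    (cardiac phase x respiratory state) binary structure masks on a
    regular voxel grid. Includes retrospective cardiac/respiratory
    signal binning, centroid and bounding-box excursion metrics,
    directed surface distance metrics (mean distance to agreement and
    95th-percentile Hausdorff distance), derivation of anisotropic
    internal organ-at-risk volume (IRV) margins, dose-volume histogram
    and near-maximum dose (D_0.03cc) evaluation, nonparametric cohort
    statistics (Kruskal-Wallis with Dunn post-hoc tests), and a
    synthetic moving phantom generator with known ground-truth motion
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
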