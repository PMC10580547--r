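Package: motorage
Title: Inertial-Sensor Motor Aging Biomarkers via a GA-Rotated Hyperspherical Projection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning hand and forearm inertial-sensor recordings
    (accelerometer, gyroscope, magnetometer at two placements) into signal
    features and a single aging biomarker. The pipeline band-pass filters each
    axis, forms the resultant magnitude, extracts 18 amplitude, frequency,
    statistical and entropy parameters per sensor and task (324 features),
    reduces them by interquartile-fence outlier handling, trial averaging and
    correlation pruning, and projects the normalized feature vectors, expressed
    in hyperspherical coordinates, onto an imaginary axis whose rotation angles
    are optimized by a real-coded genetic algorithm to maximize a pairwise
    group-separability estimator. The resulting scalar ("LDA-value") separates
    age groups and correlates linearly with age. A synthetic-cohort simulator
    with a ground-truth effect registry replaces non-public study data, and
    nonparametric screening utilities (Shapiro-Wilk, Mann-Whitney,
    Kruskal-Wallis with Bonferroni post hoc, Pearson correlation, tally
    summaries) support group analyses.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
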