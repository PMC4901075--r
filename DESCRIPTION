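Package: conjfmri
Title: Minimal-t Conjunction Analysis of Event-Related Task fMRI with
    Monte-Carlo Cluster-Extent Thresholding
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for group inference on event-related functional MRI
    across multiple decision tasks: voxel-wise general linear models with a
    canonical double-gamma haemodynamic response, run-weighted subject
    contrasts and one-sample group t-maps; seven-way minimal-t-statistic
    conjunction partitioning of task maps; Monte-Carlo estimation of
    cluster-extent thresholds that control whole-brain family-wise error;
    conjunction-derived and a-priori spherical region-of-interest response
    extraction; whole-brain spatial-correlation similarity of task response
    patterns (Pearson r, Fisher Z, paired tests); and a synthetic-cohort
    generator that plants known activation structure so that every stage of
    the pipeline is testable by parameter recovery. Includes a lightweight
    NIfTI-1 reader/writer and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
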