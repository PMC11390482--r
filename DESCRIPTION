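Package: oddball2p
Title: Prediction-Error Analysis of Two-Photon Calcium Imaging from
    Virtual-Corridor Oddball Sessions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting and quantifying sensory prediction-error
    signals in event-aligned two-photon calcium imaging recorded in a
    virtual-corridor oddball paradigm. Implements the full preprocessing
    chain (phase-correlation motion registration, ROI trace extraction,
    robust asymmetric-t neuropil decontamination, Gaussian-mixture baseline
    estimation, z-scored dF/F), event-aligned response quantification with
    threshold-based responsiveness, prediction-error and selectivity
    classification, behavior-conditioned controls (fast/slow running splits,
    running-activity correlation, pupil trace filtering), and nesting-aware
    resampling statistics (hierarchical bootstrap, randomization tests,
    bootstrap confidence intervals, Cohen's d, Bonferroni adjustment).
    Includes a ground-truth-parameterized synthetic session generator so
    every stage of the pipeline is verifiable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    boot,
    minpack.lm,
    tiff,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
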