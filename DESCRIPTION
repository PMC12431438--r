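Package: rehabDTW
Title: Markerless Rehabilitation Exercise Assessment via Dynamic Time
    Warping of Pose Landmarks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for assessing the quality of rehabilitation exercises
    from markerless pose-estimation output. Time-ordered 33-landmark 3-D
    pose trajectories are compared to a clinician reference recording with
    per-landmark multivariate dynamic time warping, aggregated into
    clinically defined joint-group distances (Head, Trunk, Shoulder),
    normalized onto an inverted 0-100 movement-quality scale, and evaluated
    against gold-standard scores with MAE, RMSE, Pearson correlation and an
    exact Wilcoxon signed-rank test. Includes a range-of-motion quality
    index, a synthetic exercise-cohort generator for end-to-end testing,
    and command-line entry points for each pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
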