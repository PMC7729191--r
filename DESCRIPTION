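Package: facekin
Title: Kinematic Predictors of Arousal Ratings from Facial Landmark Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes kinematic measures of dynamic facial expressions from
    68-landmark tracking time series (root-mean-square deviation from a
    baseline face, frame-to-frame speed, and acceleration magnitude), after
    bringing all frames into a common coordinate frame with Generalized
    Procrustes Analysis. Provides correlation-based predictor selection over
    the eight aggregated measures, within-group and between-group linear
    models of observer arousal ratings with leverage diagnostics,
    added-variable data and outlier re-fits, and a synthetic-study generator
    (landmark trajectories plus rater panels) for end-to-end validation and
    parameter-recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    yaml
Config/testthat/edition: 3
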