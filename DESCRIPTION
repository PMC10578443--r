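Package: e4episodes
Title: Detecting Stress Episodes of Obsessive-Compulsive Disorder from
    Wrist-Worn Biosensor Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting self-tagged
    obsessive-compulsive disorder (OCD) distress episodes from wrist-worn
    biosensor physiology (blood volume pulse, electrodermal activity, skin
    temperature, heart rate). Provides a synthetic cohort generator with
    known ground-truth event physiology, readers for E4-style session
    folders, sleep and non-wear filtering, event/buffer/nonevent windowing,
    a 66-dimensional physiological feature extractor, four classifier
    families including a mixed-effect random forest with per-participant
    random intercepts, nested cross-validation under random, cross-subject,
    temporal and personalized generalization scenarios, tree-path feature
    attribution, inverse-power-law learning curves for sample-size planning,
    and wear-adherence summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    ranger,
    glmnet,
    nnet,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
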