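Package: tactileRisk
Title: Predicting Risk-Taking Behaviour from Wearable Physiology During
    Human-Robot Tactile Interaction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling Balloon Analogue Risk Task (BART) scores from
    multi-rate wearable-sensor physiology (electrodermal activity, blood volume
    pulse, skin temperature and interbeat intervals in the Empatica E4 export
    dialect). Implements time-domain feature extraction (SDNN, RMSSD, skin
    conductance response counting and related measures), multicollinearity
    diagnostics (variance inflation factors and the Farrar-Glauber test) with
    lasso feature selection, a mixed-effects baseline with per-subject random
    intercepts, an RBF-kernel support vector regression baseline, and a
    multi-input convolutional multihead-attention network trained end-to-end on
    the raw signals, together with a seeded synthetic-data generator, a
    leakage-safe evaluation harness and an ablation-study driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    lme4,
    glmnet,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
LinkingTo:
    Rcpp
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
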