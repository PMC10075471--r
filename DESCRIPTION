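Package: serialdep
Title: Serial-Bias Analysis of Behavior and Multichannel EEG Epochs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying serial dependence in perceptual
    categorization experiments with simultaneous multichannel EEG. Implements
    mixed-effects logistic (GLMM) models of choice history biases with AIC
    model comparison, time-resolved cross-validated Mahalanobis-distance
    representational similarity (RSA) decoding of current- and past-trial
    features, a representational-shift statistic that measures whether the
    neural encoding of the current feature is attracted toward or repulsed
    from the previous trial's feature, and nonparametric group-level
    inference (sign-flip cluster permutation tests, lagged cross-correlation
    with max-statistic permutation thresholds, bootstrap peak-lag confidence
    intervals). A synthetic-data generator plants known serial-bias structure
    in behavior and epochs so that every stage is testable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmmTMB,
    jsonlite,
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
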