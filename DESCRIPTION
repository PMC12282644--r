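Package: agiwatch
Title: Multimodal Agitation Detection for Dementia Care
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for detecting and anticipating
    agitation and aggression episodes in people living with dementia from two
    cooperating sensing channels: a wrist-worn physiological channel (raw
    accelerometry, electrodermal activity, skin temperature and pulse rate,
    segmented into one-minute windows and summarised by a multi-domain feature
    manifest feeding Random Forest, Extra Trees, Gradient Boosting and
    multilayer perceptron classifiers) and a privacy-preserving video channel
    (14-point skeletal keypoint streams summarised by geometric
    distance/angle/point-of-reference features, reduced at a correlation
    threshold and classified by single-cell GRU and LSTM sequence models over
    sliding 30-second windows). A streaming event engine assembles window
    decisions into discrete detection events with pre/post context buffers,
    computes pre-agitation lead times against ground truth and manages an
    alert/review/retrain loop. Because clinical recordings of this kind are
    private, the package ships a synthetic cohort generator that emulates the
    documented signal regimes (pulse, activity, electrodermal and temperature
    shifts during episodes; pre-agitation ramps; pacing/rocking/kicking/
    flailing motion) so every stage is exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
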