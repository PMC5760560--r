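Package: vacommittee
Title: Committee-Machine Modeling of Music Emotion Judgments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models valence and arousal judgments of music excerpts as a
    hybrid of perceived emotion (audio features) and felt emotion
    (listener physiology). Provides a from-scratch multilayer-perceptron
    ensemble trained by batch backpropagation under genre-stratified
    cross-validation, two committee machines that combine the perception
    and feeling ensembles (an equal-weight average and a linear-regression
    stack with contribution percentages), stepwise-regression and
    random-forest comparison arms, correlation-based feature reduction,
    and a seeded synthetic-data generator that emulates the
    60-excerpt / 60-participant study design so the full pipeline runs
    end to end with no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
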