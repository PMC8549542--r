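Package: hedonometer
Title: Computational Modelling of Momentary Happiness from Reward and
    Skilled-Performance History
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling momentary happiness (affective state) as an
    exponentially discounted sum of recent extrinsic rewards and intrinsic
    (skilled-performance) rewards. Provides a simulator for a probabilistic
    reversal-learning task with a skilled cursor-navigation component held at
    a target success rate by a PEST adaptive staircase; least-squares fitting
    of a family of happiness models with BIC model comparison; parameter- and
    model-recovery pipelines on synthetic cohorts; and the accompanying
    behavioural statistics (condition splits, rank correlations, split-half
    parameter reliability).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
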