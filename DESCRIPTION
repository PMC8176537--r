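Package: pstnn
Title: Surface-Tension Neural Networks for Ordinal Psychosocial Risk Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a four-layer feed-forward neural network whose output
    layer models ordinal class membership as the breaking of liquid surface
    tensions: two hidden tanh layers feed a linear two-neuron layer whose
    outputs are interpreted as a mass and a perimeter, and four tension
    neurons with the surface tensions of ethanol, ethylene glycol, water and
    mercury convert them into cumulative risk-level activations. Ships the
    full training procedure (hand-derived error backpropagation with
    Polak-Ribiere conjugate-gradient updates and Armijo line search,
    Nguyen-Widrow initialization, gradient/goal/iteration stop criteria),
    ReliefF feature weighting with Chebyshev-metric neighbors, min-max
    normalization and stratified train/test splitting, per-class
    sensitivity/specificity/accuracy and one-vs-rest ROC/AUC evaluation with
    one-way ANOVA comparison, a synthetic psychosocial-cohort generator for
    end-to-end testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
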