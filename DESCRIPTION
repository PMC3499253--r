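Package: dnfreach
Title: Adaptive Dynamic Neural Field Model of Rule-Based Reach Decisions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates context-dependent visuomotor decision making with an
    adaptive dynamic neural field (DNF) architecture. Interconnected Amari-type
    activation fields perceive spatial and contextual cues, hold them in
    bump-attractor working memory, and competitively select reach goals;
    reward-modulated instar and outstar Hebbian rules learn arbitrary
    context-dependent visuomotor mappings. Includes the staged inferred-reach
    training protocol with a fading target cue, definite and potential
    motor-goal probe tasks, equal-probability and bias-minimizing reward
    schedules, and behavioral analyses (performance, choice fractions,
    generalization error taxonomy, training-statistics sweeps with logistic
    fits, and pseudo-population activity traces).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
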