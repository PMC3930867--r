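Package: revlearn
Title: Reinforcement Learning and Bayesian Models of Probabilistic Reversal Learning
Version: 0.1.0
Authors@R:
    person("revlearn", "maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Trial-by-trial computational models of two-alternative decision
    making under expected uncertainty and volatility: uncoupled and coupled
    Rescorla-Wagner delta-rule learners (including a win/loss-split variant
    with separate learning rates and softmax temperatures after rewards and
    punishments), a two-state hidden Markov forward filter, and a hierarchical
    Bayesian volatility filter.  Includes a generative simulator for
    probabilistic reversal tasks with controlled feedback validity and rule
    volatility, per-participant maximum-likelihood fitting with multi-start
    bounded optimization, BIC/Bayes-factor model comparison, parameter- and
    model-recovery pipelines, and reward-maximizing ("ideal agent") grid
    searches.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
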