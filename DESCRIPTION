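Package: phyturnover
Title: Phylogenetic Inference of Transcriptome Turnover from Binary
    Expression States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the evolutionary turnover of organ-specific
    transcriptomes on a time-calibrated species tree. Posterior
    probabilities of active expression (e.g. from a replicated RNA-seq
    mixture model) are discretized into ON/OFF/missing states, and a
    Bayesian two-organ correlated binary-trait model is fit by
    Metropolis-Hastings MCMC: a stationarity-normalized two-state rate
    matrix per organ, discretized-gamma among-gene rate variation, and
    bivariate-lognormal among-branch rates with an LKJ correlation prior.
    Includes exact continuous-time simulation of expression-state
    evolution, ancestral-state reconstruction, leave-k-out
    cross-validation, percent-difference-of-mean-rate (PDMR) group tests
    with a random-partition null, and cumulative turnover concentration
    curves.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
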