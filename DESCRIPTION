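Package: degcornet
Title: Degree-Correlated Cortical Network Models: Generation, Dynamics,
    Stability and Motif Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how the correlation between a neuron's
    in-degree and out-degree shapes the behaviour of model cortical
    networks.  Generates directed networks whose joint in/out-degree
    distribution is a truncated, rotated bivariate Gaussian realized by
    the configuration model (anti-correlated, positively correlated, or
    uncorrelated degrees, plus Erdos-Renyi controls); simulates the
    stochastic binary-neuron dynamics and its deterministic rate
    counterpart; analyses bistability between the low- and high-firing
    states (mean-field and finite-size critical couplings, sigmoidal
    transition fits, basin-of-attraction profiles); quantifies
    sensitivity to small-group stimulation with ROC/AUC, fuzzy c-means
    and perceptron read-outs; and performs a directed triad-motif census
    on sampled sub-networks to detect degree correlations from limited
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    methods,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
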