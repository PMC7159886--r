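Package: hccstab
Title: Stability of Degenerate Half-Center Circuits to Conductance Perturbations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates populations of two-neuron half-center circuits built from
    conductance-based (Hodgkin-Huxley style) model neurons with seven voltage- and
    calcium-gated currents coupled by graded inhibitory synapses.  Provides burst
    detection and rhythm metrics (phase difference, period, burst exclusion),
    a self-refining Monte Carlo search for functional circuits over the synaptic
    conductance grid, a global stability value quantifying robustness of the
    antiphase rhythm to single and double maximal-conductance perturbations, and
    population-level analyses including Spearman correlation of stability values
    with single-linkage reordering, ridge-penalized logistic stability classifiers
    with weight-vector geometry, and a nonlinear fit predicting double-perturbation
    stability from single-perturbation stability.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    glmnet,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
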