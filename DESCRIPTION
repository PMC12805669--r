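Package: glidetree
Title: Fixed-Topology Bayesian Phylodynamic Inference with Piecewise
    Coalescent Models and Variational Bayes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian inference of time-tree model parameters on a fixed
    rooted topology. Implements Felsenstein pruning likelihoods under
    JC69/HKY/GTR substitution models (optionally with nonreversible random
    effects under a Bayesian bridge prior), Weibull and discrete-gamma site
    rate heterogeneity, a strict molecular clock, and coalescent priors with
    constant, piecewise-constant (skygrid), and piecewise-linear (skyglide)
    demographic functions smoothed by a Gaussian Markov random field.
    Posteriors are approximated by variational inference (mean-field or
    full-rank Gaussian families, optimizing either the evidence lower bound
    or the forward Kullback-Leibler divergence via self-normalized
    importance sampling), Hamiltonian Monte Carlo, or maximum a posteriori
    optimization, with coefficient-of-variation convergence diagnostics and
    Savage-Dickey Bayes factors. A coalescent and sequence simulator
    provides synthetic data sets for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
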