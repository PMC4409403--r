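Package: corrspike
Title: Spike-Correlation Propagation, STDP and Bayesian ICA in Feedback
    Inhibitory Circuits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how spike correlations propagate through
    feedforward networks with lateral (feedback) inhibition and how they
    drive learning. Provides generators for correlated Poisson input
    (hidden Bernoulli sources filtered through gamma or exponential
    response kernels, with crosstalk mixing and synthetic auditory
    scenes), a clock-driven linear-Poisson and conductance-based LIF
    network simulator with per-synapse delays and pluggable
    spike-timing-dependent plasticity (pairwise log-STDP at feedforward
    synapses; Hebbian, anti-Hebbian and correlation-detector variants at
    lateral synapses), an analytic layer (closed-form input correlation,
    correlation-kernel coefficients obtained by quadrature, a two-source
    mean-field reduction with fixed-point and bistability analysis), a
    sequential-sampling Bayesian ICA learner, and evaluation metrics
    (delay-optimised source/output cross-correlation, mutual information,
    specialisation and selectivity indices).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    yaml,
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
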