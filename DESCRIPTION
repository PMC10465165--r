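Package: nfdcm
Title: Dynamic Causal Modelling of Self-Regulation Learning in fMRI Neurofeedback
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and Bayesian analysis of block-design fMRI neurofeedback
    experiments with a four-region (frontal, anterior cingulate, striatum,
    supplementary motor area) one-state bilinear dynamic causal model. Provides
    a compiled balloon-Windkessel forward model, variational-Laplace model
    inversion with a free-energy bound on log evidence, enumeration of the
    two-step candidate model spaces (baseline connectivity with frontal or
    striatal driving input; up-regulation modulation by source node),
    random-effects Bayesian model selection with protected exceedance
    probabilities at model and family level, Bayesian model averaging with
    learner versus non-learner group comparison, and Wasserstein-distance
    ranking of self-regulation learning from baseline and transfer runs.
    A synthetic-cohort generator with known ground truth makes every stage
    testable without access to scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    Matrix
Config/testthat/edition: 3
RoxygenNote: 7.3.3
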