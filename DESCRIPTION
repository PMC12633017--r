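Package: calatent
Title: Latent Variable Models for Calcium Imaging via a Marginalized
    Spike-to-Fluorescence Likelihood
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits latent variable models directly to calcium-imaging
    fluorescence (dF/F) traces using an observation likelihood in which
    unobserved Poisson spike counts drive an autoregressive fluorescence
    process with Gaussian noise, and the counts are marginalized out
    numerically. Provides hidden Markov models, Gaussian process factor
    analysis, and a sequential variational autoencoder with recurrent
    nonlinear dynamics, each available with the calcium likelihood or
    conventional Gaussian/Poisson baselines, together with simulators
    exporting ground truth, state/latent alignment metrics, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
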