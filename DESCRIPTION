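Package: opmsir
Title: Bayesian Inference for Stochastic SIR Models with a Time-Varying
    Infestation Rate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a stochastic susceptible-infested-removed (SIR) model with
    a time-varying, geometric-Brownian-motion infestation rate to yearly
    cumulative removal counts, as used to track oak processionary moth
    spread in managed parks. The latent epidemic is approximated by a
    linear noise approximation (LNA) whose Gaussian forward filter yields
    a tractable marginal likelihood; static parameters are sampled by
    random-walk Metropolis-Hastings, latent paths by forward-filter
    backward-sampling, and the fitted model supports within-sample and
    out-of-sample predictive simulation plus yearly basic-reproduction-
    number summaries. Includes exact Markov-jump-process and Euler-Maruyama
    simulators for generating synthetic epidemics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
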