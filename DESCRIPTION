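Package: pead
Title: Coupled Degradation-Emotion Stochastic Process Model for Alzheimer's Disease Progression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, Bayesian estimation and sequential forecasting for a
    continuous-time latent-state model of Alzheimer's disease progression in
    which an irreversible physiological degradation path (a gamma process with
    an emotion-linked shape) is coupled to a non-monotone emotional state (a
    Wiener process with bounded tanh drift driven by compound-Poisson emotional
    impacts, covariates and the degradation level), observed through a noisy
    linear cognitive score such as the MMSE. Provides a synthetic-data
    generator with the five standard parameter settings, MCMC inference with
    latent-path augmentation via JAGS, split-chain R-hat diagnostics,
    particle-filter based one-step-ahead forecasting with 5-95% prediction
    intervals, MSE evaluation, plotting, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    jsonlite,
    optparse,
    stats,
    utils,
    graphics,
    grDevices,
    parallel
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
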