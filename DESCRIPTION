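Package: camsom
Title: Multi-Species Occupancy Models for Camera-Trap Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing camera-trap surveys of interacting species:
    grouping classified images into independent detection events, building
    daily detection histories, preparing and screening site and occasion
    covariates, and fitting multi-species occupancy models in which the
    community state follows a multivariate Bernoulli distribution with
    covariate-linked pairwise natural parameters (after Rota et al. 2016).
    Models are fitted by maximum likelihood with analytic gradients; the
    package provides Wald inference, AIC-based candidate-set selection,
    derived marginal, conditional and co-occurrence probabilities, detection
    prediction curves, and a synthetic-data generator that emulates a
    staggered alpine camera-trap deployment for simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, graphics, utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
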