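Package: gripdcm
Title: Dynamic Causal Modelling of Cortical Motor Networks During Hand Grip
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating effective connectivity among cortical motor
    regions from event-related BOLD time series with bilinear dynamic causal
    models (DCM). Provides the bilinear neural state equation and a
    balloon-windkessel haemodynamic observation model with exact forward
    sensitivities, variational-Laplace model inversion yielding a free-energy
    approximation to log model evidence, enumeration of a 168-model 8-family
    hypothesis space over force-modulated couplings, fixed- and
    random-effects Bayesian model selection with family inference, Bayesian
    model averaging, paired-pulse TMS interhemispheric-inhibition statistics,
    and a synthetic-cohort generator emulating an event-related hand-grip
    paradigm with age-dependent coupling so the whole chain runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    Matrix,
    yaml
Config/testthat/edition: 3
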