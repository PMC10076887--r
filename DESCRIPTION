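Package: fedbatchkit
Title: Design and Analysis of Growth-Decoupled Fed-Batch Cultivations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing and analysing carbon-limited fed-batch
    cultivations of Komagataella phaffii (Pichia pastoris) on glycerol,
    with emphasis on growth-decoupled (pseudo-starving) recombinant
    protein production. Provides power-law slow-release substrate
    kinetics (fitting, prediction, mechanism classification),
    exponential constant-mu and constant-rate pseudo-starving feed
    design, a macroscopic ODE fed-batch simulator with growth-coupled
    and starvation-induced product-formation kinetics, black-box C-mol
    stoichiometry and respirometry (OUR, CER, RQ), estimation of
    specific rates, yields and key performance indicators from
    time-course data, carbon/electron balance data reconciliation with
    a chi-squared consistency test, a TPM gene-ranking utility, and a
    measurement-realistic synthetic-data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
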