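Package: cigrow
Title: Contact-Inhibited Growth Laws for Cell Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying how contact inhibition of proliferation
    shapes the growth of cell populations on a lattice. Provides exact
    hypergeometric occupancy probabilities for a cell's birth
    neighborhood, the mean-field growth laws that emerge in different
    migration regimes (exponential-saturating, radial/Von Bertalanffy,
    fractal, generalized logistic, Gompertz), a stochastic on-lattice
    birth-death-migration simulator, a Gillespie simulator of the
    well-mixed birth-death chain, nonlinear calibration of Gompertz and
    generalized logistic laws to confluency time series with AIC model
    comparison, a two-subpopulation competition model with invasion
    analysis, and generators of synthetic in vitro and in silico
    datasets for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
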