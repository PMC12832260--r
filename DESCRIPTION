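Package: anchorlink
Title: Anchor-Item Test Equating and IRT Parameter Recovery Simulation
Version: 0.1.0
Authors@R:
    person("anchorlink", "maintainers", email = "anchorlink@example.org",
           role = c("aut", "cre"))
Description: Tools for common-item (anchor) test equating under item response
    theory and for Monte-Carlo evaluation of how well equating recovers
    generating parameters. Provides 2PL/3PL item calibration by marginal
    maximum likelihood (EM with fixed Gauss quadrature) and EAP ability
    scoring, five scale-linking methods (mean-sigma, mean-mean,
    mean-geometric-mean, Haebara item response function, Stocking-Lord test
    response function) with chained composition for indirect equating,
    association- and error-based recovery indices with quantile trimming,
    and a factorial simulation engine over test length, anchor proportion,
    sample size and guessing probability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
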