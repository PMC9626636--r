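Package: dfiage
Title: Dynamic Frailty Indicator and Critical Dynamics of Aging from Complete Blood Counts
Version: 0.1.0
Authors@R: person("dfiage", "maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Models aging as the stochastic dynamics of a single unstable order
    parameter (a Langevin equation with a quadratic nonlinearity), and estimates
    that order parameter -- the dynamic frailty indicator (dFI) -- from
    longitudinal complete-blood-count (CBC) panels with a coupled
    autoencoder-autoregression network. Includes an SDE simulator with
    finite-time blow-up deaths and the matching closed-form survival and hazard
    laws, a synthetic multi-strain cohort generator for validation, CBC
    harmonization (granulocyte derivation, strain centering, adult-age
    filtering), PCA diagnostics, Gompertz and Nelson-Aalen mortality analytics
    with a late-life plateau check, Cox proportional-hazards benchmarking,
    rank-correlation lifespan tests, and longitudinal intervention (dFI
    increment) analysis with stratified randomization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
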