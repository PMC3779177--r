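Package: jmtrans
Title: Joint Random-Effects Transition Models for Multivariate Longitudinal Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits joint random-effects Markov transition models for
    multivariate mixed-type longitudinal panel data. Each process (ordinal,
    binary, count, or continuous) follows its own first-order (or higher-order)
    transition regression with subject-level random effects, and the processes
    are linked through a correlated multivariate normal distribution of those
    random effects. Estimation maximizes a pairwise composite conditional
    likelihood evaluated by adaptive Gauss-Hermite quadrature; inference uses
    Godambe-information sandwich covariance with Wald tests and an adjusted
    composite likelihood-ratio test. Fitted models yield subject-specific
    transition-probability matrices via empirical Bayes prediction of the
    random effects, and a simulation module generates panels with known
    parameters for calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    pracma,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
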