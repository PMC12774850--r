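Package: gprebe
Title: Dynamic Variance Components and Heritability via Gaussian Process
    Restricted Bayesian Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Posterior estimation of covariate-dependent (dynamic)
    additive-genetic and residual variance components and narrow-sense
    heritability from data with one phenotypic measurement per individual.
    Log-variance curves carry Matern Gaussian-process smoothing priors, the
    posterior is built on the restricted (REML) likelihood so fixed effects
    drop out, and sampling uses a Metropolis-adjusted Langevin algorithm
    preconditioned with the Bayesian average-information matrix evaluated at
    the maximum a posteriori estimate. Includes simulation generators for
    Gaussian-process and polynomial random-regression ground truths, a
    normalized mean-squared-error benchmark harness, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
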