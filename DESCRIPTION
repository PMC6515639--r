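Package: mvtlogit
Title: Bayesian Multivariate Latent-t Regression for Correlated Binary
    Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits a Bayesian multivariate latent Student-t regression
    model for several correlated binary outcomes observed on the same
    subjects. The latent scale is calibrated so that regression
    coefficients keep the familiar conditional log odds ratio
    interpretation of univariate logistic regression, while an
    unstructured correlation matrix captures residual dependence
    between outcomes. Includes a data-augmented MCMC sampler with a
    Metropolis correlation update, orthant-probability machinery for
    joint outcome configurations, post-hoc association measures (odds
    ratios, population risk differences, joint-configuration and
    cumulative risk contrasts), convergence diagnostics, and a
    synthetic-cohort generator for cancer-survivorship late-effects
    settings.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    mvtnorm,
    coda,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE, load = "source")
RoxygenNote: 7.3.3
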