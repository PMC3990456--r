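Package: carloglin
Title: Dependence-Structured Default Priors for Bayesian Log-Linear Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Default prior distributions for the parameters of Bayesian
    log-linear models of contingency tables in which the levels of one or
    more factors are dependent, for example geographical regions.  The prior
    is obtained by conditioning a multivariate normal distribution on the
    identifiability constraints, with identity, conditional autoregressive
    (CAR) and distance-based scale structures composed over interactions by
    Kronecker products.  Includes a data-augmentation reversible-jump MCMC
    sampler for model-averaged inference on complete and incomplete
    (capture-recapture) tables, posterior summaries (highest posterior
    density intervals, population-size posteriors, Bayes factors for
    positive spatial association, posterior predictive p-values), and
    synthetic-data generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, yaml
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
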