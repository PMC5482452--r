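Package: occuCAR
Title: Bayesian Site-Occupancy and Binomial Models with Intrinsic CAR
    Spatial Effects for Marine Risk Mapping
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Hierarchical Bayesian species distribution modelling on a
    regular lattice: site-occupancy models with imperfect detection and
    Bernoulli/binomial presence models, both with intrinsic conditional
    autoregressive (iCAR) spatial random effects, fitted by adaptive
    Metropolis-within-Gibbs MCMC. Includes a seeded synthetic-data
    generator for lattice surveys, DIC-based model selection, repeated
    train/test cross-validation with AUC and the True Skill Statistic,
    niche-overlap statistics (Schoener's D, Warren's I, Hellinger
    distance) between prediction surfaces, and a reproducible pipeline
    driver for overlap-based exposure assessment of species and vessel
    traffic.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
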