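Package: previnfer
Title: Hierarchical Bayesian Inference of Fruit Infestation Prevalence
    from Pre-Harvest Monitoring and Consignment Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers the prevalence of pest-infested fruit in a horticultural
    production system by combining pre-harvest trap-surveillance counts with
    post-harvest consignment-inspection counts across multiple production
    blocks. Implements a hierarchical Bayesian model with logit-normal block
    random effects fitted by Gibbs sampling (via JAGS), the closed-form
    single-consignment Beta-Binomial calculator with constant
    coefficient-of-variation priors, acceptance-sampling detection
    probability and trap encounter-rate estimators, a gamma-Poisson
    synthetic-data generator for simulation-based parameter recovery, and a
    config-driven scenario runner with CSV output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    rjags,
    coda,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
SystemRequirements: JAGS (>= 4.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'model-core.R'
    'inference.R'
    'closed-form.R'
    'synthetic-data.R'
    'scenarios.R'
    'io.R'
    'previnfer-package.R'
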