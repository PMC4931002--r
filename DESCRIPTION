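Package: gardenQst
Title: Hierarchical Bayesian Quantitative Genetics for Common-Garden
    Provenance Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of replicated common-garden (provenance) trials of
    forest trees and their associated arthropod communities.  Provides
    thin-plate-spline spatial detrending of field measurements, bud-flush
    phenology interpolation, Gibbs and Metropolis-within-Gibbs samplers
    for Gaussian and overdispersed-Poisson hierarchical variance-component
    models, broad-sense heritability and Q_ST estimation with Q_ST-F_ST
    divergence tests, genotype-by-environment variance partitioning,
    climate principal components and quadratic transfer functions for
    local-adaptation tests, community diversity metrics with species
    accumulation curves, and a synthetic common-garden generator with
    known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    mgcv,
    vegan,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
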