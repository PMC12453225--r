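Package: epicorrect
Title: Agent-Based Simulation of Gene-Corrected Clone Dynamics in
    Squamous Epithelium
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Stochastic lattice simulation of clonal competition in the
    basal layer of stratified squamous epithelium, built to study in situ
    gene correction of Fanconi Anemia (FA) oral mucosa. Cells divide and
    displace Von Neumann neighbours; gene-corrected cells resist
    displacement with a persistence coefficient, giving them a
    proliferative advantage over uncorrected FA cells. The package
    simulates microneedle transgene delivery (bivariate Gaussian dosing,
    weighted sampling without replacement, needle arrays), tracks clone
    fates (loss, confluence, ongoing) and expansion rates, models TP53
    mutation acquisition and genotype-specific selection on corrected and
    uncorrected backgrounds, and calibrates the TP53 persistence
    coefficient against deep-sequencing variant-allele-frequency tables
    via spatial reconstruction, window downsampling, count mean-squared
    error and interval-likelihood fits. A synthetic-data generator
    produces VAF tables with known parameters for testing and parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    Rcpp,
    yaml,
    jsonlite,
    fitdistrplus,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'RcppExports.R'
    'calibration.R'
    'cli.R'
    'params.R'
    'grid.R'
    'delivery.R'
    'engine.R'
    'epicorrect-package.R'
    'experiments.R'
    'reference.R'
    'synthetic.R'
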