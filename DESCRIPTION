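Package: polsvar
Title: Bayesian Multivariate Variance Partitioning for Pace-of-Life
    Syndrome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for individual-level analysis of multi-trait phenotype
    data from treatment-structured repeated-measures designs, as used in
    behavioural ecotoxicology. Derives behavioural, life-history and
    ejaculate phenotypes from raw measurements (scaled mass index,
    coloration proportion, count-weighted sperm velocity, haemocytometer
    counts), fits a Bayesian multivariate mixed-effects model with
    treatment-specific between-individual covariance matrices and
    treatment-specific within-individual variances via a conjugate block
    Gibbs sampler, and summarises the posterior as variance-component
    contrasts (Delta-V), between-individual (syndrome) correlations and
    repeatabilities with equal-tailed credible intervals. Includes a
    synthetic-data generator mirroring the fitted model so that the whole
    pipeline is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
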