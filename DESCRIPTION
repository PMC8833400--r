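Package: radphen
Title: Harmonized Radiomic Phenotypes for Survival Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for prognostic modelling with radiomic
    feature tables acquired under heterogeneous imaging conditions. Implements
    empirical-Bayes (ComBat) location/scale batch harmonization and a nested
    multi-batch harmonization loop ordered by Kolmogorov-Smirnov diagnostics;
    derivation of a binary imaging phenotype by principal component truncation,
    consensus clustering and complete-linkage hierarchical clustering; and
    evaluation of the phenotype's added prognostic value over clinical
    predictors with Cox proportional-hazards models, Harrell's concordance
    index with bootstrap t-approximation confidence intervals, likelihood
    ratio tests and Kaplan-Meier curves. Includes a synthetic cohort
    generator emulating a batch-distorted radiomic study with a latent
    prognostic phenotype, so the whole pipeline is testable without
    restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sva,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
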