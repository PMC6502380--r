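Package: kypemorph
Title: Morphometrics, Allometry and Variance-Component QTL Mapping of the
    Atlantic Salmon Kype
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for head morphology of sexually mature male
    Atlantic salmon reared in a common garden: TPS landmark input and
    generalized Procrustes alignment with shape PCA, log-log allometric
    adjustment of kype length and height against fork length, gonadosomatic
    residuals, REML linear mixed models with backward elimination and
    Satterthwaite type-III tests, estimated marginal means with Tukey
    contrasts, and a pedigree/IBD-based variance-component QTL linkage scan
    over a 109-SNP panel on 29 linkage groups. Includes a synthetic-cohort
    generator (pedigree, gene-drop genotypes, phenotypes, landmarks) that
    emulates the study design so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
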