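Package: ithshape
Title: Multidimensional Intratumor Heterogeneity from VAF Distribution Shape
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies intratumor heterogeneity from somatic point-mutation
    tables by summarising each tumor sample's purity-adjusted variant allele
    frequency (VAF) distribution with three shape parameters (the density-peak
    VAF, the log2 mutation count, and the MATH dispersion score), clustering
    samples into archetypes with k-medoids on principal components, comparing
    cluster-level genetics, clinical covariates and survival (Kaplan-Meier and
    Cox proportional hazards), and classifying new samples with a pruned CART
    decision tree. Includes a calibrated subclonal-architecture simulator that
    generates full synthetic cohorts (mutations, copy-number segments,
    clinical tables) so every pipeline stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    cluster,
    rpart,
    survival,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
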