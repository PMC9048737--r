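Package: dysbiome
Title: Gut-Microbiota Dysbiosis Profiling and Case-Control Discrimination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of case-control 16S gut-microbiome cohorts:
    alpha diversity (Shannon, Faith's phylogenetic diversity), phylogenetic
    beta diversity (unweighted and weighted UniFrac) with principal
    coordinates ordination and PERMANOVA, biomarker discovery by
    Kruskal-Wallis screened linear-discriminant effect sizes (LEfSe-style)
    and covariate-adjusted negative-binomial models, construction of a
    ratio-based dysbiosis index from enriched and depleted genus signatures,
    and ROC/AUC evaluation of group discrimination. Includes a
    Dirichlet-multinomial synthetic-cohort generator with planted effects so
    the whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    MASS,
    glmnet,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    picante,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
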