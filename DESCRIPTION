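Package: icpnet
Title: Pooled-Microarray Expression Profiling of Intrahepatic Cholestasis of
    Pregnancy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible re-implementation of a placental transcriptomics
    workflow for intrahepatic cholestasis of pregnancy (ICP): simulation of
    RNA-pooled microarray cohorts with planted ground truth, detection-flag
    filtering and quantile normalization, per-gene linear models with
    empirical-Bayes moderated t-statistics and Benjamini-Hochberg FDR control,
    Gene Ontology style over-representation analysis with a fold-enrichment
    ratio, Pearson co-expression and gene-interaction networks with degree and
    k-core decomposition for core-gene nomination, and the validation-arm
    statistics (delta-delta-Ct relative quantification, ANOVA with Dunnett
    post-tests, and placental morphometry aggregation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    multcomp,
    stats,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    limma,
    mvtnorm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
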