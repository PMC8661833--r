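Package: ipgs
Title: Integrated Polygenic Score Modelling of COVID-19 Severity from Coding Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-Mendelian modelling of COVID-19 severity from exome variants.
    Converts per-sample annotated coding variants into gene-level Boolean
    features stratified by allele-frequency class (ultra-rare, rare,
    low-frequency, common) and inheritance model (autosomal dominant,
    autosomal recessive, X-linked), selects features by bootstrap LASSO
    against an age- and sex-adjusted ordinal severity phenotype with a
    permutation-null inclusion threshold, combines the selected features into
    an Integrated PolyGenic Score (IPGS) with silhouette-optimised
    frequency-class weights, fits and evaluates logistic severity models
    (IPGS + age + sex) with permutation significance tests and odds-ratio
    analyses, and emits weighted gene rankings for pathway analysis. Includes
    a synthetic-cohort generator with planted variant effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    glmnet,
    MASS,
    stats,
    utils,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    vcfR,
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
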