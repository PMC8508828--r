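Package: pelitox
Title: Quantitative Toxicogenomic Toxicity Profiling with a GFP-Fused Yeast
    Reporter Library
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for reporter-based quantitative toxicogenomics:
    converts microplate OD600/GFP time series from a GFP-fused yeast stress
    biomarker library into log induction factors (ln I), time-integrated
    protein expression level index (PELI) endpoints at biomarker, stress
    category, and total levels, four-parameter logistic concentration-response
    fits with censored PELI1.5 effect concentrations, toxic equivalents
    against reference genotoxicants and oxidants, permutation gene-set
    enrichment with empirical nulls, hypergeometric ontology enrichment
    against the library reference, hierarchical clustering and PCA of
    expression profiles, and correlation of molecular endpoints with
    phenotypic assays (ROS induction, comet-assay percent Tail DNA). Includes
    a synthetic plate-data generator that emulates the assay design for
    validation and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
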