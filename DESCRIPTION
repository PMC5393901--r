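Package: pqtlpath
Title: Plasma-Protein QTL Mapping and Network Evidence for Trans Mediator Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for protein quantitative trait locus (pQTL)
    studies on multiplexed plasma-protein panels. Covers assay and genotype
    quality control, covariate residualization, genome-wide Wald scans with
    locus merging and cis/trans classification, inverse-variance fixed-effects
    replication meta-analysis with LD-proxy matching, systematic evidence
    scoring for candidate mediator genes behind trans signals (coding proxies,
    cis-eQTLs, unweighted and eQTL-weighted shortest-path permutation tests
    against a degree-preserving rewiring null, literature co-occurrence
    filters), pleiotropy clustering, and pooled disease risk-score lookups.
    A synthetic-data generator with recorded ground truth emulates the cohort,
    eQTL, network and disease-GWAS inputs so every stage can be exercised and
    validated by recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
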