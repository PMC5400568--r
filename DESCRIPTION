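Package: ceRNAforge
Title: Construction of miRNA-Mediated lncRNA-mRNA Competing Endogenous RNA
    Networks from Paired Expression Profiles
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An integrated pipeline for building a miRNA-mediated
    lncRNA-mRNA competing endogenous RNA (ceRNA) network from paired
    tumor/normal expression microarrays and a miRNA-overexpression
    response table. Provides differential expression (fold change, Welch
    t-test, Benjamini-Hochberg FDR), perturbation-response candidate
    selection, a canonical miRNA seed-match scanner with a dual-predictor
    consensus rule for miRNA response elements, coding/non-coding
    co-expression screening by Pearson correlation, tripartite network
    assembly with Cytoscape-compatible export, a from-scratch permutation
    gene set enrichment analysis (ES/NES/FDR), hypergeometric
    over-representation testing, qPCR 2^-DeltaCt relative quantification
    statistics, and a seeded synthetic-data generator with a
    machine-readable truth table for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
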