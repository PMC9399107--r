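Package: clonotrace
Title: Clonotype-Aware Statistics for Tumor Single-Cell RNA and TCR Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistics for paired single-cell RNA-seq and single-cell TCR-seq
    studies of solid tumors: quality-control filtering and log-normalization,
    cellular detection rates, z-score and bin-matched-control gene-set scores,
    tumor scores, Wilcoxon differential expression with Bonferroni correction,
    reference-relative windowed copy-number profiles and per-cell CNV burden
    scores, observed-over-expected (Ro/e) tissue enrichment, clonotype assembly
    with TCR-doublet flagging, clonal expansion, Morisita-Horn blood-tissue
    repertoire overlap, clonotype-sharing matrices, a clonal-aggregation
    permutation test, VDJ-usage PCA embeddings, and a permutation test for
    ligand-receptor interactions between tissue-enriched cell subtypes with
    cross-patient network aggregation. Includes a negative-binomial synthetic
    generator producing paired expression + TCR fixtures with planted ground
    truth, and recovery-metric reporting against that truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    methods,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
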