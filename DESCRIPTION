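Package: mircnv
Title: Case-Control Burden Analysis of MicroRNA Genes in Rare Copy Number Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for contrasting the microRNA-gene content of rare copy
    number variants (CNVs) between two patient groups, as used in studies
    that split a schizophrenia cohort by plasma pentosidine level. Provides
    sample quality control and rare-frequency filtering of CNV calls,
    annotation of CNVs with overlapping genes and miRNA genes, per-patient
    burden summaries and miRNA-enriched CNV classification, one-sided Fisher
    exact tests with Haldane-Anscombe zero-cell odds-ratio correction,
    a dominant-model genetic association power calculator, hypergeometric
    gene-set over-representation analysis for miRNA target genes, and a
    seeded synthetic-cohort simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    ggplot2,
    igraph,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rlang,
    rtracklayer,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
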