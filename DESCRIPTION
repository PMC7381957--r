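Package: lncreg
Title: Integrative lncRNA-mRNA Differential Expression and Target Regulation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully offline pipeline for integrative leukocyte
    transcriptomics: negative-binomial differential expression with FPKM and
    median-of-ratios normalisation, hierarchical clustering of expression
    profiles, Pearson coexpression screening between differential lncRNAs and
    protein-coding genes, cis/trans lncRNA target prediction combining genomic
    proximity with an RNA-RNA duplex energy scanner, lncRNA-protein interaction
    scoring from sequence-composition features, position-weight-matrix motif
    scanning for RNA-binding proteins, over-representation and preranked
    gene-set enrichment, and assembly of annotated regulatory networks. A
    synthetic-study generator with planted signals makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    igraph,
    e1071,
    randomForest,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
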