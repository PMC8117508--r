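Package: bmirnet
Title: B-Chromosome miRNA Cataloging, Coverage Screening, Differential
    Expression and Network Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the interplay between supernumerary (B)
    chromosomes and microRNAs from small-RNA sequencing data. Builds a
    miRNA catalog (adapter trimming, reference collapsing, hairpin
    detection, known/novel seed classification, arm dominance, 5-kb
    genomic clustering), screens for B-chromosome copies of miRNA loci by
    B+/B- read-coverage ratio and unaligned-read rescue, computes qPCR
    gene dose ratios by the delta-delta-Cq method, calls differentially
    expressed miRNAs with TMM normalization and a negative-binomial
    conditional exact test at fixed dispersion, predicts 3'UTR targets by
    canonical seed matching with an additive context score, and merges
    targets with a filtered protein-protein interaction network into a
    protein+miRNA graph ("B-miR-net") with integrity partitioning and
    hypergeometric GO enrichment. A synthetic-data module generates every
    pipeline input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    igraph,
    S4Vectors,
    stats,
    utils
Suggests:
    edgeR,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
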