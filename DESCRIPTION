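Package: ago2seed
Title: TLR4/NF-kB-Responsive miRNA Discovery and Ago2 RIP-Chip Target
    Triangulation
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pipeline for discovering TLR4/NF-kB-responsive microRNAs in
    ischemia-reperfusion-injured skeletal muscle and triangulating their
    target genes. Processes probe-level two-channel microarray data (QC
    flag filtering, 75th-percentile scaling for single-channel miRNA
    arrays, rank-consistency-filtered LOWESS for two-colour whole-genome
    arrays), computes replicate-level differential statistics with
    fold-change and P-value selection, classifies cross-genotype
    responsive miRNAs, clusters differential profiles (average linkage on
    Pearson distance), predicts miRNA binding sites in 3'UTRs with a
    position-weighted local duplex aligner supporting G:U wobble pairing,
    and calls targets by intersecting sequence predictions with Ago2
    RIP-chip enrichment and whole-genome downregulation. A synthetic-data
    generator with a planted ground-truth ledger makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    ape,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Transcriptomics, miRNA, Microarray, DifferentialExpression,
    Normalization, Software
RoxygenNote: 7.3.3
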