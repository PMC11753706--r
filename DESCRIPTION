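Package: fivePdecay
Title: Single-Nucleotide 5'P Degradome Profiling of Cotranslational mRNA Decay
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of 5'-monophosphate (5'P) degradome sequencing data at
    single-nucleotide resolution. Provides metagene profiles of 5'P read ends
    anchored at start and stop codons, length-normalized gene-body profiles
    with robust trimming, the per-gene frame protection index (FPI) that
    quantifies 3-nt ribosome-coupled periodicity, ratio-based decile
    clustering of genes by mutant/wild-type signal around the start codon
    (the KDIS classification), group statistics (rank-sum, hypergeometric
    overlap), and principal component analysis of strain-level relative
    expression features. A synthetic degradome generator emulates
    ribosome-coupled 5'P ends, the stop-codon ribosome pause, TSS-proximal
    accumulation of untrimmed ends, and frame-displaced endonucleolytic
    background, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    withr,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    methods,
    graphics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    GenomicAlignments,
    Rsamtools
Config/testthat/edition: 3
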