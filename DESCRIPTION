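Package: meripr
Title: Downstream Analysis of MeRIP-seq m6A Methylation Peaks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the downstream analysis of MeRIP-seq (m6A)
    experiments: IP-versus-input Poisson window peak calling with a
    transcriptome-sized background, replicate-recurrent peak
    consolidation, fraction-overlap peak set algebra between conditions,
    five-segment/20-bin metagene profiling, motif-window preparation with
    shuffled controls and IUPAC k-mer enrichment, differential
    methylation (G-test) and expression (Welch t) calling, integration of
    m6A enrichment (FPKM_IP/FPKM_INPUT) with mRNA expression, gene-set
    over-representation, and a synthetic two-condition MeRIP-seq
    generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Epitranscriptomics, Sequencing, PeakDetection,
    DifferentialMethylation, GeneExpression
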