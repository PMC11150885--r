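Package: seq2cov
Title: Base-Wise Prediction of Chromatin Accessibility and Histone
    Signal from DNA Sequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale framework for predicting per-base ATAC-seq and
    histone ChIP-seq (H3K4me3) read coverage directly from genomic DNA
    sequence. Provides the full pipeline: FASTA ingestion, four-channel
    nucleotide encoding, fixed-length zero-padded chunking with gap
    detection and blacklist masking, HDF5 dataset containers, Tn5 read
    shifting and per-base pileup, a family of convolutional and
    recurrent sequence-to-coverage architectures (U-Net, Hybrid,
    BiHybrid) trained with a masked Poisson negative log-likelihood and
    Adam, threshold peak calling with minimum length and maximum gap,
    rolling-mean smoothing, and an evaluation stack (epsilon-guarded
    Pearson correlation, base-wise peak precision/recall/F1,
    precision-recall curves with AUPRC and a fraction-of-positives
    baseline, TSS meta-profiles with an enrichment QC). A synthetic-data
    generator with planted motifs and Poisson-sampled coverage makes the
    whole system testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: HDF5 (libhdf5 headers and library)
Config/testthat/edition: 3
NeedsCompilation: yes
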