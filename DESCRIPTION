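Package: agsmeth
Title: Methylome Domain Segmentation and R-Loop Peak Analysis for AGS-Style
    Fibroblast Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream computational analyses for joint whole-genome
    bisulfite (MethylC-seq) and DRIP-seq profiling of Aicardi-Goutieres
    syndrome (AGS) fibroblast-style experiments. Provides per-cytosine
    methylation call QC and quantification (strand combining, bisulfite
    conversion rate, coverage filtering, regional methylation, binned
    tracks, TSS/TTS metaplots), a two-state hidden Markov model that
    segments methylomes into highly and partially methylated domains
    (HMDs/PMDs) with stratified random-window training, restriction
    fragment-based DRIP peak set algebra (in-silico digestion, peak
    assignment, replicate merging, common/unique classification), Monte
    Carlo feature-enrichment testing with length-matched shuffles drawn
    from the common peak set, windowed GC-skew block annotation, and
    bisulfite amplicon clone analysis. A synthetic-data generator with
    known ground truth (block-structured methylomes, multi-sample peak
    sets on a fragmented genome, bisulfite-converted clone sets) makes
    every stage testable without external sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
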