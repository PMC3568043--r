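Package: tilespp
Title: Single Position Polymorphism Detection and Diversity Analysis for
    Short-Probe Tiling Genotyping Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Parallel polymorphism discovery from short-probe (25 nt) tiling
    genotyping arrays hybridized with genomic DNA. Implements background
    correction and quantile normalization of probe-by-chip intensity panels,
    position-level integration of overlapping probes with center-weighted
    averaging, bimodal mode fitting and per-chip allele calling, replicate
    summarization (A/B/C/D/I/-), assembly of adjacent polymorphic positions
    into single-position-polymorphism (SPP) markers, post-detection filtering
    including multi-copy (paralog) flagging by flank-sequence similarity,
    validation against sequence-derived truth variants (false discovery rate,
    genotyping concordance), germplasm diversity statistics (unique alleles,
    allele-frequency matrices, gene diversity, unigene haplotypes, monomorphic
    region scans) and input writers for Structure and PHYLIP. A built-in
    hybridization simulator with planted SNPs, deletions and paralogs supports
    end-to-end testing without array data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    limma,
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
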