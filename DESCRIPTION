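Package: smorfreg
Title: Discovery, Cross-Sample Rescue, Regulation and Conservation of
    Small Open Reading Frames from Ribosome Profiling
Version: 0.1.0
Authors@R:
    person("smorfreg", "authors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for calling unannotated small
    open reading frames (smORFs) from ribosome-profiling data.  Candidate
    ORFs are enumerated by three-frame translation of an assembled
    transcriptome, scored per sample with a transparent statistic that
    combines 3-nt codon periodicity and coverage uniformity, filtered for
    novelty against an annotated reference, rescued across samples by raw
    footprint-count thresholds, classified by genomic context (uORF, dORF,
    ncRNA, intragenic, intergenic), tested for stimulus-regulated
    expression with a negative-binomial Wald test and Benjamini-Hochberg
    correction, and tiered for evolutionary conservation by translated
    (six-frame) Smith-Waterman homology search with Karlin-Altschul
    E-values.  A fully seeded synthetic-data module generates genomes,
    annotations, footprint tracks, count matrices and ortholog genomes
    with ground truth so that every stage is testable offline.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
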