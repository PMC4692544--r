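Package: tandemAPA
Title: Poly(A) Site Calling and Tandem 3'UTR Shortening Analysis from
    3'-End Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of 3'-end (poly(A)-site) sequencing data:
    internal-priming artifact filtering against the genome, gap-based
    clustering of read 3'-ends into poly(A) sites per sample, cross-sample
    merging, read-depth normalization, annotation of sites against gene
    models and known poly(A)-site catalogs, poly(A)-signal hexamer and
    nucleotide-composition profiling, per-gene standardized 3'UTR length
    indices, a linear-trend test of independence (M-squared statistic) for
    tandem 3'UTR shortening between conditions with Benjamini-Hochberg FDR,
    and Fisher exact tests for stop-codon isoform switching. Includes a
    synthetic-data generator that emulates the statistical structure the
    analysis assumes, so the whole pipeline is testable without external
    sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
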