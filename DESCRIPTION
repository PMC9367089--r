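Package: strpileup
Title: Haplotype-Resolved Read Pileups for Short Tandem Repeat Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the diploid haplotype pair most consistent with
    short reads realigned to a multi-STR locus, assigns every read pair to a
    haplotype position using fragment-length consistency, and renders a
    haplotype-resolved pileup as SVG that exposes repeat lengths,
    interruptions and genotype-quality features. Includes parsing of
    ExpansionHunter-style variant catalogs and VCFs, a tab-separated wrapper
    input path for linear BAMs, an affine-gap aligner that enumerates all
    score-tied read placements inside repeats, consensus annotation of
    repeat interruptions (e.g. AGG interruptions in FMR1 CGG tracts),
    per-locus quality-control metrics, and a paired-end read simulator so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    Rsamtools,
    GenomicRanges,
    IRanges,
    Biostrings,
    vcfR,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    xml2,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
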