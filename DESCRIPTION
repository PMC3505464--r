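Package: mirfill
Title: Small-RNA Annotation, Novel miRNA Discovery and Chip Expression
    Profiling for Developing Rice Grains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a classic plant small-RNA
    analysis workflow for the rice grain-filling phase: read cleanup
    (adapter trimming, 18-26 nt length filter, contaminant removal,
    collapsing to unique sequences), exact both-strand genome placement,
    assignment of reads to known mature miRNAs tolerating up to two
    mismatches and +/-2 nt positional variants, novel miRNA candidate
    discovery by excising genomic windows around mapped reads, folding
    them with a maximum base-pairing algorithm and applying miRNA/miRNA*
    duplex criteria (at most 3 bulges and 6 mismatches, star-read
    evidence), miRU-style miRNA target-site scoring, and miRNA-chip
    expression analysis across three grain-filling stages (detection
    calls, fold changes, t-tests, two-fold regulation classes, stage
    overlap, 2^-ddCt). A synthetic-data module generates genomes with
    planted hairpins, read populations and chip signal tables with known
    ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
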