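Package: kmapq
Title: Rare k-mer Validation and Filtering of Long-Read Alignments in Repeats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and filters false-positive long-read alignments in
    repetitive genomic regions. Rare k-mers (k-mers occurring at most m times
    across the reference) act as copy-specific markers; each alignment is
    scored by the collinearity of rare k-mers shared between the aligned
    reference and query intervals, summarised as a kMAPQ value derived from
    the longest increasing subsequence of matched reference positions.
    Includes an on-disk k-mer position database with byte-offset indexing and
    in-file binary search, PAF alignment input/output, precision/sensitivity
    evaluation against simulated ground truth, and a synthetic-data module
    that generates repeat-bearing genomes, HiFi-like and ONT-like reads, and
    alignment sets with constructed false placements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
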