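Package: gutcrispr
Title: CRISPR Cassette Discovery and Spacer-Protospacer Statistics for Gut
    Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Consensus filtering of multi-program CRISPR array predictions on
    assembled metagenomic contigs, direct-repeat clustering and cassette
    orientation, full-length spacer-protospacer matching with a mismatch
    threshold and randomized pseudospacer controls, PAM flank scanning, and
    permutation inference (leader-position Monte-Carlo test, cassette-shuffle
    spacer-sharing test, and a Cochran-Mantel-Haenszel co-occurrence statistic
    with a protospacer-shuffle null). Includes a synthetic multi-individual
    metagenome generator with a ground-truth manifest so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
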