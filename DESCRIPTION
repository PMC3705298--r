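Package: sangermerge
Title: Assemble Ordered Overlapping Sanger Sequencing Fragments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Merges two to twelve ordered, overlapping Sanger sequencing
    fragments (AB1 chromatograms or FASTA records) into a single sequence.
    Chromatogram ends are trimmed with a sliding-window quality rule, pairs
    of fragments are joined by affine-gap Needleman-Wunsch alignment of
    their overlap with per-column conflict reporting, and the chain of
    pairwise merges reproduces sequential amplicon assembly. Assemblies of
    circular genomes can be rotated so that a landmark motif starts at a
    conventional coordinate, and the merged sequence can be checked against
    reference sequences. Includes a synthetic-data generator that writes
    minimal valid AB1 fixtures from simulated genomes so the whole pipeline
    is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
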