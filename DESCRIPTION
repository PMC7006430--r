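Package: dsRNAcensus
Title: Census of Inverted and Tandem Duplicated Sequences in Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects putative intramolecular double-stranded RNA structures in
    mRNA and pre-mRNA by self-alignment, classifying duplicated sequences as
    inverted (IDS, putative dsRNA stems) or tandem (TDS, structural control).
    Provides a seed-and-extend nucleotide self-aligner and an exhaustive
    dynamic-programming reference aligner, bedtools-style interval merging with
    longest-hit nucleotide attribution, length/identity census tables, an exact
    one-sided binomial depletion test computed in log space, quantification of
    A-to-I editing (editing index, inosines per structure, residual identity)
    and of region expression (FPKM/coverage conversion) from pileups, and a
    synthetic transcriptome generator with planted ground-truth duplexes for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
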