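Package: ghostseek
Title: Seed-and-Extend Translated Homology Search for Short Reads
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Maps short DNA sequencing reads (roughly 60-75 bp) against a
    protein database in the style of a translated (BLASTX-like) search.
    Reads are translated in all six frames, anchored to the database via a
    chunked k-mer inverted index with skip-sampled query keys and
    region-bucketed candidate detection, and scored with Smith-Waterman
    local alignment restricted to a small window around each candidate
    position. Includes an exhaustive Smith-Waterman oracle, a synthetic
    read/database simulator, and a sensitivity evaluation harness, plus a
    two-subcommand command line interface and BLAST tabular output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
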