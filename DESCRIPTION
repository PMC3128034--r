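Package: mapbench
Title: Formally Defined Gold Standards and Evaluation for Read Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds formally defined gold standards for the read mapping
    problem and evaluates the output of arbitrary SAM-producing read mappers
    against them. A match of a read in a reference is an equivalence class of
    end-anchored semi-global alignments: per-position error landscapes are
    flooded to a water level of k + 0.5, the resulting lakes are merged by
    trace equivalence (shared leftmost-minimal start positions), and every
    class is stored as a (k, first, last) interval triple. Mappers are scored
    in the all, all-best and any-best categories with the normalized found
    intervals metric. Includes a brute-force reference implementation of the
    equivalence definitions, a seeded interval-extension builder that only
    inspects a fraction of the reference, a small haplotype/read simulator
    producing FASTQ plus an origin SAM for the biological problem, and
    deterministic repeat-structure fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    withr,
    jsonlite,
    yaml,
    Biostrings,
    GenomicAlignments,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
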