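Package: nullomeR
Title: Identification and Analysis of Nullomers and Nullpeptides
Version: 1.0.0
Authors@R:
    person("nullomeR", "Developers", email = "nullomer-dev@example.org",
           role = c("aut", "cre"))
Description: Detects absent words (nullomers) in genomes and their functional
    compartments, and absent peptides (nullpeptides) in proteomes, using dense
    presence bitmaps over the full k-mer space.  Provides negative-selection
    scoring of absent words (substitution-neighbour occurrence means, k-let
    preserving Monte Carlo shuffles, cross-species absence ratios, and an
    aggregate rank score), genome-wide maps of single-base mutations that
    materialize nullomers, intersection with population variants and
    allele-frequency based resurfacing probabilities, population-specific
    nullomer calls, and absence-based phylogenetics via Jaccard distances and
    Ward clustering.  Includes seeded synthetic-data generators and brute-force
    oracles so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    rtracklayer,
    VariantAnnotation,
    ape,
    data.table,
    jsonlite,
    optparse,
    withr,
    Rcpp,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
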