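Package: fourmer
Title: Four-Mer Prefiltered Smith-Waterman Protein Database Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A BLAST-like two-stage heuristic for searching protein queries
    against a protein database. A fast exact-match prefilter packs every
    4-mer (four consecutive residues) of a subject sequence into a 32-bit
    code and flags subjects showing a local concentration of query 4-mer
    matches, tracked over a 16-position sliding window (the "nearby"
    register). Only subjects that pass the filter are aligned with exact
    Smith-Waterman local alignment under affine gap penalties (Gotoh
    recurrences, compiled core). Supports reduced amino-acid alphabets built
    by frequency-based agglomerative clustering (21 down to 15 letters), a
    non-exhaustive fast mode that indexes subject 4-mers at even offsets
    only, deterministic batched parallel database scanning, a command-line
    interface, and a seeded synthetic-data generator with planted homologs
    for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    optparse,
    withr,
    parallel,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
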