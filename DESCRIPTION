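Package: motifEnrich
Title: Promoter Motif Enrichment Against Composition-Matched Simulated Nulls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decides whether a promoter region is non-randomly enriched in
    short transcription-factor binding motifs of the Churchill (NGGGNN) type.
    Counts consensus-pattern occurrences, simulates a composition-matched
    random-sequence null ensemble, scores sites with a position weight matrix
    log-likelihood ratio against the background model, and compares observed
    and null sequences with a one-sample Z-test, a compound-Poisson /
    Monte-Carlo global enrichment test, replicated Kruskal-Wallis rank tests
    on site quality, a Monte-Carlo Beta A/B success-rate comparison, and a
    sliding-window positional enrichment profile. Includes a synthetic
    promoter generator with planted motif clusters for calibration and
    power checks.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
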