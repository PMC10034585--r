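Package: profscan
Title: Protein-Family PSSM Construction, Compositional-Bias Masking and
    Proteome Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds sensitive family-specific position-specific scoring
    matrices (PSSMs) from curated sets of divergent protein homologs via
    master-slave alignment, position-based sequence weighting and
    pseudocount-mixed log-odds scores; detects and hard-masks
    compositionally biased regions (FG repeats, low-complexity tracts) by
    optimal ungapped alignment against homopolymers; scans proteomes with
    position-specific Smith-Waterman search under Karlin-Altschul
    E-value statistics with optional composition-based rescaling; and
    benchmarks detection sensitivity (true-positive and false-negative
    rates, rank-of-true-hit matrices) against an expected-composition
    gold standard, ingesting both native BLAST-tabular and HMMER tblout
    results. Includes a seeded synthetic-family generator that provides a
    download-free benchmark surface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
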