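Package: pufselect
Title: In Vitro Selection Simulation, Binding-Element Counting, and
    Affinity Analysis for PUF RNA-Binding Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the RNA sequence specificity of
    Pumilio/FBF-family (PUF) RNA-binding proteins and their partner
    complexes. Simulates in vitro selection (SELEX/SEQRS) of random RNA
    libraries under an equilibrium-occupancy retention model, scans reads
    for compact (8-nt) and extended (9-nt) degenerate binding elements
    anchored at the UGU trinucleotide, computes per-position-+4
    compact:extended ratio statistics and position frequency matrix motif
    summaries, fits electrophoretic mobility shift assay (EMSA)
    titrations with the one-site specific binding model to estimate
    dissociation constants and relative affinities (Krel), and tests
    motif-stratified gene sets for functional-term enrichment with the
    hypergeometric test and Benjamini-Hochberg correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
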