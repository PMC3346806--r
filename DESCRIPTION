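Package: chemoscan
Title: 3D Protein-Family-Profile Screening for Remote Chemokine Homologs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A filter cascade and simplified knowledge-based threading engine
    for proteome-scale discovery of remote structural homologs of the IL8-like
    chemokine fold. Candidate sequences are pre-filtered by annotation keywords,
    cysteine content, homology to structurally characterized proteins and
    consensus signal-peptide/transmembrane trimming; survivors are threaded
    onto a chemokine fold library and a redundancy-reduced all-fold library
    with pair and burial potentials of mean force, scored with a composite
    threading index, and classified by fold-coverage, gap and secondary
    structure rules. Query cysteine pairs are mapped onto the template scaffold
    with geometric disulfide criteria, and candidate models are evaluated with
    per-residue contact energies, structural superposition and secondary
    structure fractions. Seeded generators for toy templates, homologs and
    decoy cohorts make every stage testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    bio3d,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    rlang,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
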