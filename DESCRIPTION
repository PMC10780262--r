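Package: dockQM
Title: Docking-Based Quantitative Matrices for Peptide-HLA-DQ Binding Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives position-specific quantitative matrices (QMs) for peptide
    binding to celiac-disease-associated HLA-DQ molecules from molecular-docking
    affinities of single-amino-acid-substitution (SAAS) combinatorial peptide
    libraries. Provides SAAS library construction, parsing of docking output and
    energy-range pose filtering, mean-normalization of best affinities into
    per-position amino-acid contribution coefficients, additive binding-core
    scoring of peptides and whole proteomes, non-binder decoy generation, and
    sensitivity/specificity/accuracy cutoff scans. A seeded synthetic docking
    simulator with a planted additive energy model makes the entire workflow
    reproducible and testable without a docking engine.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
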