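Package: clonotracer
Title: Single-Cell V(D)J Clonotype Tracing for Plasma-Cell Dyscrasias
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of immunoglobulin V(D)J clonotypes in
    plasma-cell dyscrasias. Provides a synthetic repertoire generator
    (junctional diversity, somatic hypermutation, nonsense-mediated decay,
    barcoded and UMI-tagged reads, consensus-primer bulk amplicons), a
    single-cell clonotype caller (UMI/barcode consensus building, germline
    V/J assignment by semi-global alignment, CDR3 extraction at conserved
    anchors, productivity classification, clonotype grouping), clonality
    statistics, concordance analysis between single-cell RNA and bulk-DNA
    amplicon clonotyping with mechanistic attribution of discordances, a
    primer 3'-mismatch annealing screen, and in silico minimal residual
    disease spike-in detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
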