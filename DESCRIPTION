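Package: picoresp
Title: Single-Cell Respirometry and Expression Heterogeneity from Sealed-Microwell Sensor Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extraction of single-cell oxygen consumption rates (OCR) from
    ratiometric luminescence-quenching sensor time series recorded in
    hermetically sealed picoliter microwells, cluster-enrichment statistics
    (total enrichment score and relative variability) quantifying changes in
    gene-expression heterogeneity under repeated hypoxia selection, and
    OCR-augmented embeddings (PCA, t-SNE) for identifying cells with aberrant
    combined functional and transcriptional phenotypes. Includes a forward
    simulator of the full study design - sensor drawdown kinetics, a 96-gene
    single-cell expression panel with dropout, and bottleneck selection with
    re-expansion - so every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rtsne,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
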