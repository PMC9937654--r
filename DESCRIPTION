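Package: ibioid
Title: Proximity-Labeling Proteomics Analysis of Axonal Release Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for in vivo biotin identification (iBioID)
    proximity proteomics of presynaptic release sites. Takes long-format
    peptide-count tables from multi-bait BirA experiments, removes
    mitochondrial and purification contaminants, computes session-wise
    fold change over a soluble-axon reference bait with pseudocount
    imputation of zero session averages, averages fold changes across
    mass-spectrometry sessions, and calls enriched proteins at
    configurable thresholds. Downstream tools cover three-bait overlap
    (Venn) partitions, ontology-category summaries with two-way ANOVA
    and Bonferroni post-hoc genotype comparisons, curated gene-panel
    reports, and export of node lists for external network analysis.
    A negative-binomial synthetic-data generator with planted ground
    truth and a synaptosome image quantification module (Otsu
    segmentation, size gating, ROI classification and intensity
    comparison) make every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
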