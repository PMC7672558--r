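Package: hypoflux
Title: Bioenergetic Flux, Transcriptome and qPCR Analysis for Cellular
    Hypoxia Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for two-condition (normoxia/hypoxia) cell
    culture experiments combining extracellular-flux bioenergetics with
    transcriptomics. Derives mitochondrial stress-test metrics
    (mitochondrial respiration, coupled respiration, proton leak, spare
    respiratory capacity) and glycolysis metrics (non-glycolytic and
    glycolytic acidification, glycolytic capacity and reserve) from
    plate-format oxygen-consumption and extracellular-acidification time
    series, with sulphite-referenced low-oxygen rate correction and
    cell-number (DNA-fluorescence) normalization. Provides a
    normality-gated two-group testing layer with a reciprocal-logit
    transform for percentage metrics, fold-change/p-value filtering of
    log2 expression matrices with hypoxia-panel and immune-family
    reporting, hypergeometric/EASE over-representation analysis, PCA
    sample QC, delta-delta-Ct relative quantification, and seeded
    synthetic-data generators for flux plates, expression matrices and
    paired Ct tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nortest,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
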