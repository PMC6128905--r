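Package: proxiscreen
Title: Dual-Screen Inference of Isoform-Specific Protein Vulnerabilities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantification and integration of BioID proximity-labeling
    proteomics with pooled CRISPR-Cas9 loss-of-function screens, as used to
    nominate RAS isoform-specific vulnerabilities. Provides peptide-to-protein
    aggregation with robust-mean, carboxylase and BirA normalization schemes,
    positive-control-calibrated interactome calling, per-guide depletion
    metrics with best-3-of-5 gene-level collapse and reference-benchmarked
    classification, dual-assay hit integration, gene-set over-representation,
    and synthetic-data generators that emulate both assays with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1),
    SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
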