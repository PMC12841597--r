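Package: panepiclock
Title: Pan-Epigenetic Aging Clocks from Gene-Level Histone and DNA Methylation Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Harmonizes ChIP-seq histone-mark peak calls and whole-genome
    bisulfite CpG tables into gene-level feature matrices shared between
    human and mouse, quantifies coordinated age-related change across
    epigenetic layers (per-gene Spearman age associations, top-k overlap
    enrichment, cross-layer crosstalk statistics), trains single-layer and
    pan-epigenetic gradient-boosted age clocks under donor-grouped
    age-stratified cross-validation with leakage-safe inverse normal
    transform batch correction, and analyzes per-donor aging-rate
    synchronization and caloric-restriction effects on age-prediction
    residuals. Ships a synthetic-cohort generator with a machine-readable
    truth set so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    xgboost,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
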