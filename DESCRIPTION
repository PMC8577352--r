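Package: markerscore
Title: Cutoff-Anchored Scoring and Hierarchical Classification of Cell-Type Marker Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Normalizes heterogeneous per-study marker-gene statistics
    (log fold changes, adjusted p-values, AUROCs, ...) to a common [0,1]
    score anchored at 0.5 on each study's own significance cutoff, and
    classifies each gene as a cell-type marker, higher-level marker,
    non-marker, or indeterminate using a pruned hierarchical cell
    ontology, cross-source aggregation, and a mouse/human species
    specificity rule. Includes a synthetic corpus generator with planted
    ground-truth markers, flat-file (CSV/JSON) pipeline stages, and a
    command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
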