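Package: evmeta
Title: Differential Expression and Exhaustive Multi-Dataset Comparison for
    Extracellular-Vesicle Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for label-free extracellular-vesicle (EV)
    proteomics. Implements per-protein two-sample t-tests on log2 intensities
    with Benjamini-Hochberg false-discovery-rate control and fold-change
    classification; overlap counting of a detected proteome against reference
    EV catalogs such as ExoCarta and Vesiclepedia; an exhaustive
    multi-dataset comparison algorithm that enumerates every combination of
    two or more protein-set datasets, restricts to anchor datasets, collapses
    comparisons sharing an identical common-protein set, ranks them, and
    scores each with a Simpson condition-type diversity index; a local
    hypergeometric over-representation test against GMT annotation sets; and
    a seeded synthetic-data generator so every stage runs without external
    downloads. All user-facing functions take and return tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    patchwork,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
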