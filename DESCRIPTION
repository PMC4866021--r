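Package: mirlink
Title: Link miRNAs to Experimentally Validated Targets with Set Enrichment
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Links user-supplied miRNA identifier lists and UniProt-annotated
    target lists to experimentally validated miRNA-target interactions (MTIs)
    pooled from several source databases. Provides miRBase-style nomenclature
    parsing and semantic identifier matching at configurable stringency,
    harmonization of heterogeneous target symbols to UniProt accessions in
    species-specific or species-agnostic (homology) mode, multi-criteria
    interaction filtering (database occurrence, species, validation method,
    CLIP support), per-miRNA target-set assembly with occurrence-string
    matrices and overlap heatmaps, and an optional MTI-set enrichment analysis
    over a user-ranked target list (weighted running-sum enrichment score,
    permutation-based normalized enrichment score, FDR q-values, and
    leading-edge extraction). A seeded fixture generator produces synthetic
    reference databases and ranked lists with known planted structure so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
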