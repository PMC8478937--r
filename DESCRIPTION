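Package: pgxlandscape
Title: Pharmacogene Variant Landscape Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies pharmacogene variants by rarity and predicted
    function, summarizes genetic variability per gene and gene family
    (including aggregated functional-variant frequencies), and compares
    variant allele frequencies across populations with Bonferroni-corrected
    contingency tests. Ships a synthetic variant-table generator with known
    ground truth so the whole pipeline is testable without access to
    restricted cohort data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
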