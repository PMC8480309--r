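Package: translag
Title: Delayed Protein-Level Changes from Multi-Omics Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of the lag between translation and protein abundance
    across a germinating-seed time course measured on three molecular layers
    (total mRNA, polysomal mRNA, protein). Implements consecutive-time-point
    differential expression with empirical-Bayes variance moderation,
    time-lagged per-gene Spearman correlation between layers, classification
    of delayed-response up-/down-regulated genes (DUGs/DDGs) with +1/+2/+3
    contrast shifts, sequence-feature and decay-rate comparisons, exact
    position-weight-matrix scanning, and Fisher/hypergeometric motif and GO
    enrichment. Ships a synthetic multi-omics generator with planted ground
    truth so the whole pipeline can be exercised and scored end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
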