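Package: promvar
Title: Design and Analysis of Promoter-Variant Reporter Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A toolkit for massively parallel reporter assays (MPRAs) that
    dissect cis-regulatory variants in yeast promoters. Covers oligo-block
    and barcode library design, barcode-to-oligo dictionary construction
    from merged amplicon reads, barcode counting and per-oligo expression
    quantification, per-variant allelic activity tests with empirical-Bayes
    variance moderation, epistasis (interaction) tests for variant pairs,
    linkage-disequilibrium statistics, allelic transcription-factor
    binding-site feature scoring from position weight matrices,
    single-feature and cross-validated multi-feature models of variant
    causality, and comparison of aggregated variant effects against local
    eQTL effects. Includes a synthetic-data generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    stringr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    caret,
    pROC
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    withr
Config/testthat/edition: 3
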