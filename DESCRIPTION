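Package: mpravar
Title: Design and Analysis of Massively Parallel Reporter Assays for Variant Fine-Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for fine-mapping regulatory variants
    with massively parallel reporter assays (MPRA). Designs variant-centered
    oligo libraries with full allelic permutations for co-occurring variants,
    builds barcode-to-fragment dictionaries from paired-end association reads,
    normalizes and filters per-barcode counts, quantifies per-barcode and
    per-fragment reporter activity, tests fragments for allele-specific
    activity against their reference-allele counterparts, and prioritizes
    hits by linkage disequilibrium with lead GWAS SNPs. Ships a synthetic
    data generator with known ground truth so every stage can be exercised
    end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    stats,
    Biostrings,
    vcfR,
    generics,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
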