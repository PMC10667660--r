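Package: isgquant
Title: Absolute Amplicon Quantification with Synthetic Internal-Standard Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Design of synthetic internal-standard genes (ISGs) that carry
    binding sites for multiple phylogenetic and functional marker primer sets
    (16S rRNA, pmoA, amoA), IUPAC-aware in-silico PCR and cross-match
    screening, negative-binomial dose-response calibration with the slope
    fixed at one for converting amplicon read counts to absolute gene copy
    numbers, limit-of-quantification flagging, read-recovery and
    GGC-motif/GC-content diagnostics, and a seeded generator of synthetic
    spike-in libraries with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
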