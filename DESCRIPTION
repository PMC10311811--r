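Package: hapcompare
Title: Reference-Free Pairwise Comparison of Haplotype Assembly Outputs
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Compares the phased outputs of diploid haplotype assembly
    programs against each other, without requiring true haplotypes. Reads
    HapCUT2-style block files (including the MixSIH, PEATH, SDhaP and
    MAtCHap dialects) and phased VCFs, normalizes them to a common
    site-per-row representation, and computes block-by-block agreement,
    block and SNV disagreement rates, and a panel of twelve switch-distance
    metrics for every ordered pair of tools. Also provides gold-standard
    position-overlap reports, position-restriction filtering, fragment-level
    read-depth filtering, and a synthetic diploid phasing generator whose
    corruption log predicts every downstream comparison metric exactly.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
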