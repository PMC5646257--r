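Package: straindrift
Title: Strain Divergence Screening and Biofilm Founder Back-Calculation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracing unintended laboratory evolution in bacterial
    cultures, motivated by biofilm-deficient lineages of Desulfovibrio
    vulgaris Hildenborough. Implements a read-frequency and strand-bias
    acceptance rule for resequencing variants with cross-sample
    classification (shared, strain-unique, emergent), codon-consequence
    annotation of single- and multi-nucleotide substitutions, a
    multi-criteria proteome screen for type I secretion system (T1SS/RTX)
    cargo proteins (size, isoelectric point, cysteine scarcity,
    hemolysin-type calcium-binding repeats, GGXGXDXXX nonamers near the C
    terminus), and a founder-population back-calculation for biofilm
    reactors, together with synthetic-data generators (pileups, proteomes,
    reactor trajectories) so every stage can be exercised without external
    downloads. All user-facing functions take and return tidy data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
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
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
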