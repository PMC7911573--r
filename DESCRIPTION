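Package: itspcr
Title: In Silico PCR Evaluation of Fungal ITS Metabarcoding Primers
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in silico PCR engine for evaluating fungal ITS metabarcoding
    primer pairs against UNITE-style reference databases. Locates degenerate
    (IUPAC-aware) primer binding sites under configurable mismatch-acceptance
    rules (mismatch budget, no long consecutive runs, protected 3' terminus),
    extracts amplicons within length bounds, and estimates per-site melting
    temperatures from a nearest-neighbor duplex model. Downstream summaries
    report per-taxon coverage percentages, unidentified-taxon counts per rank,
    per-phylum representation, and amplicon-length comparisons (Welch t-test).
    Includes a deterministic synthetic-database generator with planted primer
    sites and a machine-readable truth table for end-to-end validation.
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
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
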