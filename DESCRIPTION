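Package: anchorscreen
Title: Genome-Scale Screening of Surface-Display Anchor Proteins in
    Gram-Positive Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts membrane topology and N-terminal export signals for
    every protein in a Gram-positive proteome, assigns one of seven
    subcellular-localization classes and a secretion pathway, applies a
    configurable screening rubric for candidate surface-display anchor
    proteins, and emits a ranked candidate table with N/C anchoring-site
    assignment. Includes a compact cyclic hidden Markov model for
    per-residue inside/membrane/outside posteriors, heuristic detectors for
    Sec (SPI), lipobox (SPII), twin-arginine (Tat) and LPXTG sortase
    signals, a synthetic-proteome generator with planted, labelled export
    features, and embedded reference tables of known and candidate anchors
    of Corynebacterium glutamicum.
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
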