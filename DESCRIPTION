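Package: velvetarch
Title: Velvet Domain Architecture from Column Conservation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to resolve the architecture of fungal velvet domains from
    large sequence collections: profile (PSSM) alignment against a seed
    alignment with match/insert column bookkeeping, per-column conservation
    scoring by Jensen-Shannon divergence with gap penalty and window
    smoothing, sequence-logo information content in bits, segmentation of the
    conservation profile into DNA-binding, variable and dimerization
    (alpha-linker-beta) regions, per-sequence region-length statistics,
    reference-coordinate mapping for alanine-scanning plans, and a minimal
    structure utility for dimer-interface contact distances. Includes a
    synthetic velvet-family generator with planted architecture so every
    stage is testable without the full dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
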