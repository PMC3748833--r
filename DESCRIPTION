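Package: wavefold
Title: Minimum Free Energy RNA Secondary Structure Prediction by
    Wavefront Dynamic Programming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts minimum free energy (MFE) secondary structures of RNA
    sequences under a nearest-neighbor thermodynamic model. The dynamic
    programming tables are filled in anti-diagonal (subsequence-length)
    order so that all cells of one diagonal are mutually independent, with
    a deterministic traceback, hard folding constraints (forced and
    prohibited pairs, forced single-stranded positions), SHAPE reactivity
    pseudo-energies, selectable helix-end energy modes (dangling ends or
    terminal mismatches), and an optional neighbor-pair prefilter. Includes
    readers and writers for FASTA, CT and dot-bracket formats, a plain-text
    thermodynamic parameter dialect, base-pair sensitivity and selectivity
    accuracy metrics with the compatible-pair correction, and an exhaustive
    enumeration oracle for verifying the engine on short sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    tibble,
    generics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
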