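Package: shapecrf
Title: Protein Backbone Shape-String Prediction from NMR Chemical Shifts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts eight-state protein backbone shape strings (a
    structural alphabet over Ramachandran regions) from per-residue NMR
    chemical shifts and sequence-derived shape-string profiles using a
    linear-chain conditional random field. Includes a strict reader and
    writer for SHIFTY-dialect chemical-shift tables, min/max
    normalization and ten-letter alphabetization of shifts, hallmark
    sequence-pattern mining with binomial conservation tests, profile
    construction from exact k-mer hits, segment-overlap (SOV) and
    S8/S3 accuracy scoring with bootstrap errors, a leave-one-feature-out
    ablation harness, and a synthetic corpus generator so the full
    pipeline runs without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    Matrix,
    Rcpp,
    Biostrings,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
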