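Package: bandstripe
Title: Banded Striped Pairwise Sequence Alignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Global pairwise nucleotide alignment combining banded dynamic
    programming with a striped vector layout. The band is re-laid-out between
    rows by a striped move (register rotation plus a one-lane shift), row
    scores are evaluated with an affine-gap difference recurrence relation,
    and within-row horizontal-gap dependencies are resolved by a two-pass
    active F-loop. Also provides a Myers-style bit-vector edit-distance
    engine with whole and limit modes, brute-force Gotoh, Smith-Waterman and
    Wagner-Fischer oracles, a read-error simulator with configurable
    substitution:insertion:deletion ratios and structural indel injection,
    a recall benchmarking harness, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    optparse,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
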