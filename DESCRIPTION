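Package: crpcna
Title: Copy Number Aberration Detection with a Conditional Random Pattern Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects copy number aberrations (CNAs) on ordered log2-ratio
    sequences from SNP arrays using a conditional random pattern (CRP)
    sequence model: distance-dependent transition potentials built on
    Haldane's map function, a pattern-based local evidence function that
    scores each locus against all candidate minimum-run CNA patterns, and
    exact Viterbi / forward-backward inference with per-locus posteriors.
    Includes log2-ratio feature extraction from intensity tables via
    best-fit reference averaging, simulators reproducing the standard
    validation designs at log2-ratio level, and a seven-metric
    (SNP-, region- and hybrid-level precision/recall plus f-score)
    evaluation scheme. Tidyverse-native interface with tidy(), glance()
    and autoplot() methods, plus a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
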