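Package: divergene
Title: Candidate-Gene Discovery for Divergently Bred Mouse Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable implementation of a transcriptome-to-locus
    candidate-gene discovery pipeline for mouse lines selectively bred for
    divergent behaviour (high- vs low-anxiety lines). Covers two-colour
    microarray normalization (MA transform, global median, intensity-dependent
    loess, sub-array balancing, dye-swap orientation), permutation-based
    differential expression with step-down maxT adjusted p-values, a
    single-channel path with quantile normalization and a moderated
    t-statistic, cross-region candidate selection rules, 2^-ddCt qPCR relative
    quantification with housekeeping normalization, allelic variant
    annotation, tallying and density-cluster scanning against a gene model,
    and nonparametric multi-group statistics (Kruskal-Wallis, Mann-Whitney,
    Holm step-down). A synthetic-data module generates every input with known
    ground truth so all stages are testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    Rcpp,
    yaml,
    limma,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
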