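Package: erpool
Title: Evolve-and-Resequence Pool-Seq Inference for Replicated Selection Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for evolve-and-resequence experiments with pooled
    whole-genome sequencing of replicate populations under two selection regimes.
    Provides a Wright-Fisher forward simulator with two-stage pool sampling and
    linkage blocks, sync-format count-table input/output with heuristic SNP-calling
    filters and coverage subsampling, windowed nucleotide diversity and Tajima's D,
    effective-population-size estimation from among-replicate allele-frequency
    variance with a pool-seq correction factor, a two-pronged candidate-SNP scan
    (Fisher exact tests on pooled counts and binomial mixed models) with
    permutation-based empirical false discovery rates, delineation of linked
    candidate-SNP clusters from within-regime residual correlations, allele
    frequency pattern classification, and multi-set intersection, SNP-permutation
    category enrichment and matched network randomization tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0),
    lme4,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
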