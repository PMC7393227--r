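Package: stresscape
Title: Stress-Response Transcriptomics of a Marine Picocyanobacterium
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated, reproducible pipeline for stress-response
    time-course transcriptomics in marine picocyanobacteria. Provides a
    synthetic-data generator with planted ground truth (negative-binomial
    counts with latent module structure, planted fold changes, genome-ordered
    annotations with co-expressed gene runs, trait tables, PAM-fluorometry
    kinetics and phycobilisome emission spectra), negative-binomial
    differential expression with Benjamini-Hochberg correction, signed
    weighted gene co-expression networks with module eigengenes,
    module-trait correlation and partial-least-squares VIP filtering,
    exclusive intersection-set classification of differentially expressed
    genes, detection of genomically adjacent co-expressed gene runs
    ("cyanorons"), and photosystem II physiology calculators (Fv/Fm,
    repair-rate estimators, emission-peak ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    withr,
    minpack.lm,
    rtracklayer,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    mclust,
    mixOmics
Config/testthat/edition: 3
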