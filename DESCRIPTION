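Package: epimark
Title: Multi-Omic Integration of DNA Methylation, Chromatin Marks and
    Expression in T-Cell Reprogramming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidy toolkit for dissecting the epigenetic basis of T-cell
    reprogramming from tabular genomics inputs. Calls differentially
    methylated regions (DMRs) from per-CpG bisulfite counts using pooled
    Fisher exact tests with fold-change and minimum-CpG criteria, predicts
    active enhancers as open chromatin regions carrying H3K27ac outside
    promoters, annotates features to gene bodies, promoters and TSS
    windows, tests the association between epigenetic marks and
    differential expression with one-sided chi-square statistics,
    classifies genes into epigenetic co-occurrence groups, and summarises
    paired-chain TCR clonotype structure. Ships seeded synthetic-data
    generators with ground-truth manifests so every caller can be scored
    against known answers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
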