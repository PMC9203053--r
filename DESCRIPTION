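Package: retromem
Title: Semantic Relatedness and Retroactive Memory Effects in Paired-Associate Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for paired-associate cued-recall experiments that
    measure retroactive interference and facilitation as a function of semantic
    relatedness. Provides semantic-relatedness metrics over free-association
    networks and word-embedding vectors (associative strength, backward mediator
    strength, weighted path length, bounded spreading activation, cosine
    similarity); generators for counterbalanced two-list stimulus designs and
    retrieval-to-criterion or yoked study-only learning schedules; a synthetic
    subject-data generator encoding a reminder-based account of
    relatedness-dependent recall; per-pair memorability, joint-retrieval
    dependence with mismatched-duo null thresholds, intrusion and
    learning-efficiency metrics; smoothed bivariate "Osgood" surfaces with
    cluster-based permutation inference; and supporting repeated-measures
    statistics (Huynh-Feldt corrected ANOVA, FDR pairwise tests, item-level
    regression, partial correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
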