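Package: la3switch
Title: Switch-Gene Discovery by Three-Way Liquid Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end discovery of "switch" genes whose expression level
    controls the co-expression of a gene pair, via the binned modified
    liquid-association (MLA) statistic. Provides a seeded synthetic-data
    generator that plants switch triplets and differentially expressed
    genes into a two-class expression study; preprocessing (quantile
    normalization, IQR probe collapse, empirical-Bayes moderated-t gene
    filtering); a genome-scale triplet scan with permutation or normal
    significance and top-K retention; an event-rate diagnostic with a
    binomial non-random-occupancy flag; random-forest permutation
    importance (mean decrease accuracy) with out-of-bag ROC evaluation;
    hypergeometric gene-set enrichment with a shared-term triplet rule;
    an ARACNE-style mutual-information network with data-processing-
    inequality pruning and triplet path support; Kruskal-Wallis
    clinic-pathological association; and a reproducible pipeline that
    composes the stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    limma,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
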