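Package: prefnr
Title: Paired-Comparison Analysis of Preferred Noise-Reduction Strength
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for forced-choice paired-comparison studies of
    hearing-aid noise-reduction (NR) strength. Enumerates balanced AB/BA
    paired-comparison designs over a grid of maximum gain-reduction (Gmin)
    levels, tallies per-level win counts, and fits the quadratic-utility
    logistic (QUL) preference model per listener to estimate the preferred
    strength with uncertainty. Includes response-feature group statistics
    (Kolmogorov-Smirnov, Bartlett, Kruskal-Wallis with Dunn-Bonferroni post
    hoc, Spearman correlation, and the two-sample power calculation),
    Ward/Manhattan hierarchical clustering of win-count profiles with
    dendrogram stability ranking, a resampling simulation of the number of
    paired comparisons needed to classify a listener into the correct
    preference cluster, and a seeded synthetic-cohort generator that emulates
    the study design for end-to-end testing.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    mclust,
    nortest,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
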