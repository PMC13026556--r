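Package: lectnet
Title: Differential Co-Expression Networks and Survival Stratification for
    Gene Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds per-condition Spearman co-expression networks from gene
    expression count matrices, scores every gene pair with a Fisher
    Z-transformation based differential z-score, calls differential networks
    and degree-percentile hub genes, validates hub agreement across cohorts,
    and stratifies subjects by hub-gene expression (fuzzy C-means or median
    splits) for Kaplan-Meier survival comparison with log-rank tests and
    Mantel-Haenszel hazard ratios. Includes median-of-ratios count
    normalization, Welch t-test differential expression with
    Benjamini-Hochberg correction, and a Gaussian-copula negative-binomial
    simulator with planted differential hubs and linked survival outcomes for
    end-to-end validation.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
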