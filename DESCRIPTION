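Package: zscreen
Title: Consensus Gene Prioritization from Multi-Phenotype Z-Statistic Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prioritizing genes and gene-phenotype associations from a
    matrix of association z-statistics, as produced by CRISPR drug-resistance
    screens or multi-omic prognostic association studies. Implements three
    row-outlier (consensus) ranking procedures - Fisher's method, the sum of
    squared z-statistics (SSz), and a robust cellwise minimum covariance
    determinant (cellMCD) estimator with Mahalanobis row-outlier p-values and
    entry-outlier standardized residuals - together with p-value calibration
    diagnostics (uniform quantile-quantile data, RMSD lack-of-fit, 99%
    inclusion boundaries), a contaminated multivariate-normal simulator, and an
    AUC benchmarking harness. Includes tidy() / glance() accessors, ggplot2
    autoplot() methods, and a command-line interface.
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
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
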