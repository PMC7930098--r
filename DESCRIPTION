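Package: mixqtl
Title: Combined Total and Allele-Specific Count cis-eQTL Mapping, Fine-Mapping
    and Expression Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A log-linear approximation splits haplotype-resolved RNA-seq
    counts into two approximately independent regressions: an allelic-imbalance
    equation driven by allele-specific reads and a total-read-count equation.
    The package fits both per variant and combines them by inverse-variance
    meta-analysis for fast cis-eQTL scans, stacks the variance-standardized
    equations into one augmented dataset for multi-SNP fine-mapping (a minimal
    sum-of-single-effects solver producing posterior inclusion probabilities
    and credible sets) and for penalized genetic prediction of expression
    (elastic net via glmnet). A generative simulator of phased genotypes and
    haplotype-resolved read counts, and an evaluation harness for type I
    error, power, calibration and prediction accuracy, are included.
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
    glmnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
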