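Package: hsmscan
Title: Haplotype-Specific Methylation Scanning and CpG-SNP Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrated genotype-epigenotype analysis for tiled methylation
    data on a fixed 100-bp window grid. Computes regional methylation load
    and tests its association with SNP genotype (Kruskal-Wallis, linear
    regression with an age covariate, and permutation empirical p-values),
    localises haplotype-specific methylation with a multi-scale sliding
    window scan, calls case/control differentially methylated regions with
    an empirical-Bayes global test (random-coefficient logistic model,
    score statistic, Storey q-values and permutation FDR), and provides a
    CpG-creating SNP toolkit (YpG/CpR classification, ancestral gain/loss
    polarity, in-phase clustering, haplotype CpG-capability counts, LD
    metrics, and bisulphite-pyrosequencing table re-analysis). A synthetic
    cohort generator with known truth supports calibration and recovery
    testing of every stage.
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
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
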