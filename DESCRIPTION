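Package: eqenrich
Title: Equivalent Change Enrichment Analysis Across Paired Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how similarly individual genes respond to two
    different treatments with the equivalent change index (ECI), the signed
    ratio of the smaller to the larger effect size across two
    treatment-versus-control experiments, and identifies biological pathways
    concentrated in equivalently or inversely changed genes with a weighted
    Kolmogorov-Smirnov enrichment test (ECEA) using gene-sampling permutation
    nulls, normalized enrichment scores and Benjamini-Hochberg false discovery
    rates. Includes single-experiment enrichment and over-representation
    intersection baselines, a correlated-block expression simulator with
    planted equivalent, inverse and differential-expression-only pathways,
    and a benchmarking harness that scores sensitivity and false-positive
    rate against the simulated ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    fgsea,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
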