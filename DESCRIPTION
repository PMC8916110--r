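Package: agefc
Title: Age-Related Functional Connectivity Analysis with Network-Based
    Statistics and Bootstrap Mediation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-scale analysis of resting-state functional
    connectomes: construction and proportional thresholding of ROI-by-ROI
    correlation matrices, network-level mean functional connectivity,
    covariate-adjusted linear models with standardized coefficients and a
    Bonferroni family threshold, the network-based statistic (NBS) with
    permutation family-wise-error control over maximal connected-component
    size, and parallel-mediator mediation analysis with non-parametric
    bootstrap inference. Includes a synthetic-cohort generator that emulates
    the statistical structure of a middle-aged to older epidemiological
    imaging cohort (age-correlated cortical thickness, white-matter peak
    width of skeletonized mean diffusivity, Trail Making Test scores, and
    connectomes with planted age-related subnetworks) with known ground
    truth for recovery testing.
License: MIT
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
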