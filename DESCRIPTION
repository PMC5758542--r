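Package: modgain
Title: Brain-Network Modularity and Intervention-Related Cognitive Gains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline linking baseline resting-state brain-network
    modularity to intervention-related executive-function gains in older
    adults. Builds Fisher-z functional-connectivity matrices and
    density-thresholded binary graphs from ROI time series, computes
    Newman-Girvan modularity under spectral or canonical partitions along
    with weighted module segregation, applies framewise-displacement motion
    quality control, scores multi-test cognitive batteries into construct
    composites and standardized gain scores, and fits moderated regressions
    and partial correlations with bias-corrected and accelerated (BCa)
    bootstrap confidence intervals. A synthetic cohort generator with
    planted brain-behavior effects supports parameter-recovery testing of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    boot,
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
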