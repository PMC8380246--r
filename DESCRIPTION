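Package: rnatraj
Title: Trajectory-Based Discovery of Treatment-Emergent Expression Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying peripheral gene-expression markers whose
    change during antidepressant treatment tracks clinical response.  The
    pipeline classifies depression-score (MADRS) trajectories into early,
    later and non-response, screens RNAs through a three-criterion funnel
    (baseline case-control differential expression, correlation with symptom
    change at endpoint, no baseline correlation), fits a linear latent growth
    model per RNA with SEM fit indices (CFI, TLI, GFI, RMSEA, SRMR), and
    relates per-subject expression slopes to response status through binary
    and multinomial logistic regression with false-discovery-rate control.
    Includes a synthetic-cohort generator with the longitudinal and
    negative-binomial count structure the analysis assumes, longitudinal
    k-means clustering with Calinski-Harabasz model selection, and the
    supporting group-comparison and qPCR (2^-ddCt) statistics.
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
    MASS,
    multcomp,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    nnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
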