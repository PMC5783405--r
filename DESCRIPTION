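Package: bnconsensus
Title: Consensus Bayesian Networks for Microbiome and Survey Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns consensus discrete Bayesian networks linking microbial
    presence/absence, demographics, behavioural survey responses and clinical
    scores. Provides the full analysis pipeline: count and survey filtering,
    depth normalization, dichotomization and discretization; BDeu-scored
    constrained hill-climbing structure learning with imaginary-sample-size
    estimation; bootstrap arc-strength ensembles and thresholded averaged
    networks; maximum-likelihood conditional probability tables with exact
    variable-elimination queries and Markov blankets; graph metrics (density,
    degree, normalized closeness and betweenness, Louvain communities); and
    companion community-ecology analyses (Hellinger transform, NMDS, ANOSIM,
    PERMANOVA with forward stepwise AIC selection). A layered synthetic-data
    generator emulates the joint structure of such studies so that structure
    and parameter recovery can be quantified end to end.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
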