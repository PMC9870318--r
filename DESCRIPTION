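Package: patchtype
Title: Intrinsic-Property Phenotyping of Patch-Clamp Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates, measures and classifies intrinsic electrophysiological
    phenotypes of projection neurons recorded in whole-cell patch clamp.
    Provides a conductance-based single-compartment simulator for four
    firing phenotypes (regular, rebound-bursting, non-sagging, and
    late-firing "Others" cells) under standard current-clamp and
    voltage-clamp step protocols; feature extraction for voltage sag,
    rebound spiking, hyperpolarization-activated current (Ih) density,
    maximum firing rate before depolarization block, spike latency and
    inter-spike intervals, and passive membrane properties; rule-based
    neuron-type classification with exclusion criteria; Ward (ward.D2)
    hierarchical clustering of feature matrices with heatmap and dendrogram
    output; and the accompanying ANOVA/Tukey statistical surface. All
    user-facing functions take data frames and return tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    stats,
    utils,
    generics,
    car,
    ape
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    yaml,
    optparse,
    withr
VignetteBuilder: knitr
LinkingTo: Rcpp
Config/testthat/edition: 3
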