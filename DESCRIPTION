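Package: hippsplit
Title: Split-Circuit Hippocampal Network Models of Object and Context Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Rate-coded neural network models of the hippocampal circuit
    (lateral/medial entorhinal cortex, dentate gyrus, CA3, CA1) with
    k-winners-take-all inhibition and two-phase contrastive Hebbian learning,
    for studying how anatomical differentiation -- the posterior/anterior
    split, the superior/inferior blades of the dentate gyrus, and the
    distal/proximal subdivisions of CA3 and CA1 -- supports the joint use of
    object and context information in recognition memory. Includes a
    synthetic binary pattern generator with additive-noise, non-additive
    noise, partial-cue and context-mismatch corruption benchmarks, declarative
    builders for five architecture variants, and a reproducible experiment
    harness (training, crossconnection sweeps, test batteries, layer-size
    sweeps) with tidy outputs and ggplot2 figure helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
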