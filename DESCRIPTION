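Package: tcellgater
Title: Quantile-Gated T-Cell State Calling and Spatial Proximity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based annotation of tumour-infiltrating T-cell clusters from
    single-cell RNA-seq summary profiles (75th-percentile and mean positivity
    gating for regulatory, senescent and exhausted states), marker-threshold
    annotation of mass-cytometry metaclusters from per-marker normalised
    heatmaps, and spatial proximity statistics for phenotyped tissue maps
    (banded nearest-neighbour distance histograms, truncated-lognormal fits
    with geometric means, co-localisation fractions and compartment
    infiltration densities). A synthetic-data module plants ground-truth
    cell states and spatial structure so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stats,
    jsonlite,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
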