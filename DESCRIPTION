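Package: biomeclock
Title: Dating Biome Origin and Latitudinal Spread from Sister-Species
    Divergence Times
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to estimate the age and latitudinal spread of a biome
    from the divergence times of within-biome sister species on a dated
    ultrametric phylogeny. Extracts same-biome sister pairs (cherries)
    with their node ages and HPD intervals, fits upper-quantile linear
    regressions of divergence age on mean latitude with Markov chain
    marginal bootstrap uncertainty, measures phylogenetic signal in
    binary biome membership with the D-statistic (permutation and
    Brownian-threshold nulls), projects pair ages onto a regular
    latitude-longitude grid, and simulates trees, biome labels and
    latitudinal ranges with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
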