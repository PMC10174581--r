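Package: keystone
Title: Keystone Species Identification in Quantitative Food Webs via
    Tabu Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates threshold-based secondary extinction cascades in
    quantitative (energy-flux weighted) food webs and identifies keystone
    species by optimising a network disintegration objective with tabu
    search.  Provides classical centrality-based removal protocols
    (in-degree, out-degree, their sum and product, eigenvector), the
    secondary extinction curve with its area statistic (SEA) and the R50
    robustness index, threshold sweeps, a niche-model synthetic web
    generator with a brute-force optimal-removal oracle, and a comparison
    harness with one-way ANOVA and Dunnett many-to-one contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    multcomp,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
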