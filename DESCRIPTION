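Package: lakewalk
Title: Correlated Random Walk Simulation of Smolt Migration Through Lakes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates downstream-migrating Atlantic salmon smolts searching
    for the lake outlet with a correlated random walk bounded by the
    shoreline. Provides planar geometry primitives (point-in-polygon,
    segment-region intersection, outlet capture-region sizing from an
    exposed-perimeter target), parameterized hypothetical basin builders and
    approximate real-lake fixtures, a boundary-collision turning-angle
    inflation rule, factorial simulation grids over step length and
    turning-angle dispersion with success/distance/passage-time surfaces,
    and a statistical layer: binomial GLMs with likelihood-ratio model
    selection and odds ratios, chi-squared contingency comparisons,
    Kruskal-Wallis with Dunn post hoc tests under Holm-Bonferroni
    correction, and comparison of simulated grids against telemetry
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
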