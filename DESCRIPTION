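Package: bioblitzr
Title: Quantitative Analysis of Bioblitz Outcomes from Biodiversity Event Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the outcomes of bioblitzes (short, place-based
    biodiversity recording events) from observation and identification event
    logs. Qualifies candidate projects against the bioblitz definition
    (multiple observers, at least one identifier, bounded duration), computes
    per-project summary statistics, measures the post-event boost in
    participant recording activity with a seasonality-controlled paired-week
    design, fits an exponential decay model of the boost with project-level
    heterogeneity (half-life, cumulative additional recording days, platform
    extrapolation), builds the observer-identifier bipartite network of an
    event, and scores multi-rater aim rankings with Jaccard agreement. A
    seeded synthetic event-log generator makes every stage testable without
    platform downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    minpack.lm,
    igraph,
    yaml,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
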