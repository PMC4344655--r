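Package: seascaper
Title: Biophysical Seascape Bioregionalization with Self-Organizing Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Delineates biophysical marine environments from gridded ocean
    fields. Derives per-pixel climatological variables (long-term mean and
    climatological extreme sea surface temperature, chlorophyll a, current
    speed, salinity), assembles a range-standardized pixel-by-variable feature
    table, clusters pixels with a batch self-organizing map over a scan of
    hexagonal lattice topologies, selects the best partition by mean silhouette
    index, and characterizes the resulting classes. A seeded synthetic-data
    generator produces gridded inputs with planted contiguous regimes so the
    full pipeline runs and is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    cluster,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
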