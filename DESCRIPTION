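Package: activnet
Title: Network Autocorrelation Models for Physical Activity in Friendship
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing accelerometer-measured physical activity and
    sedentary time within school friendship networks. Builds directed,
    row-standardised weight matrices from friend nominations, processes
    per-epoch accelerometer counts into daily and per-child summaries using
    non-wear detection and intensity cut points, computes Moran's I
    diagnostics with permutation inference, fits network autocorrelation
    (spatial lag) models by maximum likelihood with direct/indirect/total
    impact decompositions, and handles missing data via chained-equations
    multiple imputation with Rubin's rules pooling. Includes a synthetic-data
    generator emulating a cohort of primary-school children so the full
    pipeline runs without access to restricted study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    methods,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    optparse,
    sandwich,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
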