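Package: tdoatrack
Title: Acoustic Localization and Tracking of Vocal Wildlife from
    Time Differences of Arrival
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Locates calling animals (e.g., rutting sika deer) from the time
    lags at which the same call is detected by three or more synchronized,
    stationary sound recorders.  Positions are retrieved by an exhaustive
    grid search that minimizes the root-mean-square error between observed
    lag distances and those predicted at each candidate point under a
    flat-earth (equirectangular) projection.  Includes a forward simulator
    of propagation delays, annotation-timing noise and distance-dependent
    audibility; tools to collapse repetitive calls from the same territorial
    individual by spatial single-linkage clustering; per-interval call
    statistics and movement-path summaries; and CSV/GeoJSON/KML input and
    output with a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    optparse,
    withr
Config/testthat/edition: 3
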