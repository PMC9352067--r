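Package: flywaynet
Title: Migratory Networks from Light-Level Geolocator Stationary Estimates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds annual-cycle migratory networks for Arctic-breeding
    shorebirds from light-level geolocator stationary estimates. Provides
    rule-based track refinement (proximity merging, pre-departure and polar
    filtering, turning-angle cleaning), segmentation of tracks into south
    migration, winter, and north migration periods, per-period migration
    parameters (initiation and arrival dates, duration, minimum distance,
    speed, stop statistics), diameter-constrained k-medoid regionalization
    of stops into flyway regions, season-specific weighted network and
    daily-occupancy construction, pairwise Fisher exact and Wilcoxon
    rank-sum comparison batteries, and a ground-truth-annotated synthetic
    track generator emulating geolocator-style positional error and
    artifacts.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    geosphere,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
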