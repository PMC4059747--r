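Package: vmstrack
Title: Processing and Analysis of Vessel Monitoring System and Logbook Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to process satellite Vessel Monitoring System (VMS) pings and
    logbook catch records into cleaned fishing trips, interpolated trajectories,
    metier classifications and spatial fishing-pressure indicators. Includes
    configurable delimited-text loaders with an SQLite-backed store, warning-code
    based ping cleaning (duplicates, on-land positions, speed/heading checks,
    harbour buffers), harbour-to-harbour track cutting, speed- and
    heading-informed cubic Hermite interpolation onto a shared time grid,
    bathymetry and area enrichment, metier discovery by k-medoids (PAM/CLARA)
    clustering of catch profiles under the Bray-Curtis dissimilarity with the
    number of clusters chosen by average silhouette width, fuzzy classification
    against medoid profiles, temporal-overlap linkage of VMS tracks to logbook
    trips, neural-network metier prediction from track behaviour, fishing-point
    detection by speed/depth/harbour-distance thresholds, gridded effort maps,
    Data Collection Framework pressure indicators 5 and 6, and trawled-area
    estimation. A seeded synthetic-fleet generator provides ground-truth data
    for every pipeline stage.
License: GPL (>= 2)
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    DBI,
    RSQLite,
    geosphere,
    mclust,
    nnet,
    pracma,
    sp,
    stats,
    utils
Suggests:
    cluster,
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
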