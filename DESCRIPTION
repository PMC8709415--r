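Package: actiweek
Title: Clustering Whole-Week Wrist-Accelerometer Activity Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for turning weekly wrist-accelerometer epoch series
    (5-second ENMO summaries in milli-gravity units) into 168-hour activity
    profiles and clustering them with k-medoids. Includes quality
    classification of weekly series into the five usable completeness
    categories, imputation of daylight-saving-time transition weeks,
    wear-time and mean-activity exclusion filters with a reconciled
    selection funnel, hourly aggregation and Monday-aligned week rotation,
    Euclidean and dynamic-time-warping distances with a metric-agreement
    report, a from-scratch PAM (BUILD + SWAP) k-medoids implementation
    with a dissimilarity scree and a first-difference rule for choosing
    the number of clusters, cluster composition and outcome
    cross-tabulation tables, and a synthetic-cohort generator with nine
    archetypal diurnal/weekly activity patterns for testing every stage
    without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    cluster,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
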