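Package: fcmscreen
Title: Fuzzy Cognitive Map Inference and Path-Based Screening for
    Environment-Disease Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Learns higher-order fuzzy cognitive maps (FCMs) from daily
    multivariate environmental and hospital-admission time series by
    differential evolution under a directional-feedback mask that forbids
    disease-to-environment edges, then screens environment-disease and
    disease-disease relationships on the learned signed digraph using
    simple-path counts and aggregated simple-path weights. Includes a
    synthetic-data generator with seasonal, collinear environmental
    factors and negative-binomial admission counts driven by a known
    ground-truth FCM, multicollinearity diagnostics (variance inflation
    factors), and a reproducible end-to-end study pipeline with CSV,
    JSON and GraphML outputs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
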