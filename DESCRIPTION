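Package: lpindex
Title: Multi-Species Population Trend Indices with Diversity Weighting
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes multi-species abundance indices of the Living Planet
    Index family from sparse population time series. Population trends are
    estimated with generalized additive model smoothing (six or more
    observations) or chain-method log-linear interpolation, averaged within
    species, and aggregated through an unweighted hierarchy (tropical and
    temperate zones by system) or a diversity-weighted hierarchy (taxonomic
    groups weighted by their share of known species within each realm and
    system). Includes percentile bootstrap confidence intervals by species
    resampling, chi-squared tests of taxonomic and Red List representation
    against reference species counts, a synthetic data generator with known
    ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    mgcv,
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
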