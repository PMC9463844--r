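Package: svyscan
Title: Spatial Scan Statistics for Complex Health-Survey Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Circular spatial scan statistics for geographic cluster
    detection on population-based health-survey data. Implements the
    Bernoulli likelihood-ratio scan for individual-level binary responses
    and the weighted normal scan for region-level rate estimates, with
    Monte Carlo inference, non-overlapping secondary clusters, and
    Gini-coefficient selection of the maximum reported cluster size.
    Includes a full simulation framework: synthetic study regions with
    age-by-sex stratified census populations, complex-survey sampling with
    design and post-stratification weights, construction of frequency,
    weighted-frequency and aggregate crude-rate inputs, and
    sensitivity/positive-predictive-value evaluation of detected clusters
    against known true clusters.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
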