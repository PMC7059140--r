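Package: kcml
Title: Weakly Supervised Gene-Function Classifiers for Perturbation Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trains one weakly supervised classifier per Gene Ontology term on
    gene-perturbation phenotypic profiles (image-based or expression screens),
    selects trustworthy classifiers by explicit false-positive-rate and recall
    thresholds, and uses them to rank context-dependent gene-function
    predictions genome-wide. Includes the profile-construction statistics
    (scaled rank-sum and Kolmogorov-Smirnov distances, distribution-shape
    summaries), screen preprocessing (missingness cleaning, feature k-NN
    imputation, plate normalisation, cell-number confound correction),
    annotation propagation and term-catalog filtering, clustering- and
    correlation-based baselines, siRNA seed off-target filtering, term-overlap
    network construction, interaction-network enrichment, and a synthetic
    screen generator with planted ground truth for offline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    igraph,
    jsonlite,
    stats,
    utils,
    Rcpp,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
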