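Package: stscreen
Title: Spatiotemporal Analysis of Cancer-Screening Participation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring participation in organized cancer-screening
    programs across space and time. Builds neighborhood-by-biennial-period
    participation panels from georeferenced invitation records (including a
    fully offline fuzzy geocoder against a building registry), stabilizes
    small-area rates with spatial empirical Bayes smoothing, detects
    participation clusters with the Getis-Ord Gi* statistic under
    k-nearest-neighbor weights and Monte-Carlo permutation inference, classifies
    each neighborhood's space-time trajectory with emerging hot spot analysis
    (space-time cube, FDR-corrected bin statistics, Mann-Kendall trends, a
    17-category rule table), scores physical accessibility to screening centers
    as a linear-decay density over street-network distances, and fits an
    interpretable gradient-boosting model of area-level participation
    determinants with Shapley attributions. A synthetic-canton generator with
    planted spatiotemporal patterns provides ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    deldir,
    sp,
    FNN,
    igraph,
    jsonlite,
    yaml,
    xgboost,
    kernlab,
    lhs,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
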