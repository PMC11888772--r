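Package: bstmap
Title: Battleship-Technique Scoring of Articular Surface Distance Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies intraarticular contact patterns of the talar dome
    from weight-bearing CT distance maps. Computes inter-surface distance
    maps from triangulated bone surface meshes, scores a 16-square grid
    into the distance-map weighted-sum point (TWSx, TWSy) using the
    Battleship technique, and classifies coronal (varus/valgus) and
    sagittal (anterior/posterior) contact patterns. Includes the
    accompanying statistical toolkit -- single-measure two-way random
    absolute-agreement intraclass correlation with confidence intervals,
    normality-gated group comparisons and correlations, and an a-priori
    ICC sample-size calculation -- together with a synthetic joint and
    cohort generator with known ground truth for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
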