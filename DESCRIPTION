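Package: shapecorr
Title: Semantic-Part Correspondence Between Closed 2D Contours
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts point-to-point correspondences between closed planar
    contours from semantic part structure, contour-curvature surprisal, or
    uniform arc-length sampling, and evaluates the predictions against human
    (or simulated) dot-matching responses. Provides arc-length contour
    geometry, von Mises turning-angle surprisal profiles, dynamic time
    warping of contour profiles, part-label vote aggregation and label
    matching across shape pairs, congruity and order-preservation response
    statistics, paired t / Wilcoxon / JZS Bayes-factor model comparison,
    correspondence-driven shape morphs, and a fully seeded synthetic-data
    generator for labeled animal-like outlines and simulated observers.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
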