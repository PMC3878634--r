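Package: dietlp
Title: Food Pattern Modeling of Sodium and Potassium Feasibility by Linear Programming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds nutritionally constrained diet-optimization problems from
    intake-survey and food-composition tables and solves them by linear
    programming. Maps the feasible (sodium, potassium) region of a sex-age
    group by sweeping a fixed daily sodium level, finds the potassium-maximal
    pattern at a fixed Na:K mass ratio, finds the nutritionally adequate
    pattern closest (weighted L1) to observed eating habits, and tests the
    effect of an across-the-board reduction in the sodium content of the food
    supply. Ships a seeded synthetic-data generator emulating the structure of
    national intake surveys and food-composition databases, plus tiny
    hand-solvable fixtures, so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    boot,
    ggplot2,
    withr
Config/testthat/edition: 3
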