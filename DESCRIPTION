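Package: snpmeals
Title: Nutrient Evaluation and Menu Optimisation for Supplementary
    Nutrition Programme Meals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to evaluate meals served to preschool children through
    India's Integrated Child Development Services Supplementary Nutrition
    Programme (ICDS-SNP). Computes per-child daily nutrient provision from
    menu cycles and food-composition tables (with staple-fortification
    overlays and moisture adjustment), summarises state-level provision and
    simulates its distribution under a lognormal model, scores adequacy
    against the 2012 and 2023 programme standards and ICMR rules
    (digestibility-adjusted protein, fat-to-energy band, one-third EAR with
    a 10% flexibility margin, traffic-light bands), and optimises menus by
    linear programming under a per-child budget. Ships a synthetic data
    generator so the whole pipeline is testable without survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    boot,
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
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
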