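Package: vaoptim
Title: Least-Cost Planning of Vitamin A Fortification and Supplementation Programs
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for subnational economic optimization of vitamin A
    intervention portfolios over a multi-year planning horizon. Simulates an
    EHCVM-style household consumption survey, models child dietary vitamin A
    inadequacy from household nutrient density, computes the effective-coverage
    and cost streams of large-scale food fortification (edible oil, bouillon
    cube) and macro-regional supplementation programs, enumerates every
    feasible program package, solves the least-cost package selection problem
    across a grid of coverage targets under discounting, and assesses the
    robustness of optimal packages to stochastic benefits and costs by Monte
    Carlo simulation with quantile-binned frequency-of-optimality summaries.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
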