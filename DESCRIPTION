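Package: sarcocea
Title: Lifetime Cost-Utility Modelling of Sarcopenia Management Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A decision-tree plus Markov cohort model for the lifetime
    cost-utility analysis of sarcopenia management strategies (exercise,
    protein and vitamin D supplementation, whole-body vibration, and their
    combinations) in an elderly population. Interventions act by reducing
    fall risk through improvements in muscle mass, strength and physical
    performance; falls lead to fractures with first-year excess mortality,
    costs and disutility. The package fits Beta, Gamma and Log-normal
    parameter distributions from published moments, synthesises a Gompertz
    background life table, runs the cohort engine per strategy and arm,
    performs incremental cost-effectiveness analysis on the efficiency
    frontier, and quantifies uncertainty through net-monetary-benefit
    tornado analysis, probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, and the expected value of
    perfect information.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
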