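Package: ironintake
Title: Dietary Iron Intake, Adequacy, and Biofortification Scenario Projection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates individual dietary iron intake from two-day food
    diaries with recipe-level attribution of the wheat- and rice-derived
    components, assesses adequacy against a sex- and age-specific
    population reference intake (PRI) schedule, and projects intake under
    climate-change grain-iron depletion, biofortification, and
    wholegrain-substitution scenarios with a confidence-interval
    half-width significance rule. Includes a calibrated synthetic
    dietary-survey generator emulating a national two-day diary survey,
    group summary statistics, and a tie-corrected Kruskal-Wallis
    comparison layer.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
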