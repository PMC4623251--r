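Package: footcea
Title: Decision-Tree Cost-Effectiveness Analysis of Diabetic-Foot Prevention
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A prevalence-based decision-tree model of secondary prevention of
    diabetic foot ulceration in a high-risk cohort. Propagates the cohort
    through ulceration, care-setting and clinical-endpoint branches for three
    prevention strategies (sub-optimal care, standard care, standard care plus
    daily foot-temperature monitoring), computes direct cost of illness by
    ingredients-based costing, values premature mortality with the
    human-capital approach, derives incremental cost-effectiveness ratios with
    dominance classification and a GDP-multiple threshold, and runs one-way
    deterministic sensitivity analyses rendered as tornado orderings. Includes
    a generator of internally consistent synthetic parameter sets for
    property-based testing and a bundled Peru-2012 parameter fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    yaml,
    jsonlite,
    graphics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
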