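Package: deacare
Title: Input-Oriented Data Envelopment Analysis for Fragmented Health Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the technical efficiency of health-care providers with
    input-oriented data envelopment analysis (DEA) under constant or variable
    returns to scale, and aggregates unit-level scores into the institutional,
    state and national summaries used to benchmark fragmented public health
    systems. Includes a self-contained envelopment-form solver with a
    second-phase slack maximization, independent verification oracles
    (multiplier form, one-dimensional closed form, coarse ratio grid),
    threshold classification of decision-making units, efficiency-gap and
    annual-variation summaries, rank correlation of state efficiency with GDP
    per capita, a synthetic-panel generator with known ground-truth
    efficiencies, and bundled reference tables for obstetric-care delivery by
    Mexico's six federal public health institutions over 2012-2018.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
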