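Package: fortiplan
Title: Vitamin D Food Fortification Planning and Serum Response Modelling
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes constant and seasonally varying vitamin D fortification
    levels for carrier foods (bread, milk, juice, or custom carriers) from
    population consumption percentiles, dietary intake data and either intake
    recommendations (IOM, DGE, tolerable upper level) or 25-hydroxyvitamin D
    serum targets. Forward-models the resulting monthly 25(OH)D serum
    trajectories through a linear intake-to-serum conversion factor, builds
    percentile-based risk envelopes for extreme consumers, and derives intake
    multipliers across consumption percentiles. Includes a calibrated
    single-harmonic synthetic generator for monthly baseline 25(OH)D
    trajectories and a deterministic scenario-grid pipeline with CSV/JSON
    reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
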