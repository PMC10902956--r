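Package: rrmmcea
Title: Cost-Utility and Budget-Impact Modelling of Triplet Therapy in
    Relapsed-Refractory Multiple Myeloma
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A three-state Markov cohort model (progression-free,
    post-progression, death) for the cost-utility comparison of
    daratumumab versus carfilzomib triplet regimens (DRd vs KRd) in
    relapsed-refractory multiple myeloma, from a payer perspective.
    Baseline monthly hazards are exponential and calibrated to a
    restricted life-year target for the comparator arm; the intervention
    arm is derived through hazard-ratio transforms of the cause-specific
    hazards.  The package computes discounted costs, QALYs and life
    years, incremental cost-effectiveness statistics (ICUR, ICER, ACER,
    net monetary benefit), one-way deterministic sensitivity analysis
    with tornado ordering, price-threshold analysis, probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves,
    and a five-year budget impact model with market-share displacement.
    An individual-level microsimulation over the same transition
    structure serves as a brute-force validation oracle and as a
    generator of synthetic patient-level survival data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse
Config/testthat/edition: 3
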