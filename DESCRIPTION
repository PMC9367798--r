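Package: lesim
Title: Land-Use Simulation Under Ecological Security Constraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating future land-use patterns under ecological
    security constraints. Computes a grid-based land ecological security
    index by catastrophe-progression aggregation of pressure-state-response
    indicators with entropy weighting, classifies the landscape into
    ecological zones by natural-breaks partitioning, derives constraint
    factor weights for land conversion from binary logistic regressions,
    builds multi-criteria suitability atlases by weighted linear
    combination, and allocates Markov-projected class demands spatially
    with a cellular automaton. Includes map-agreement validation (Cohen's
    kappa), change and zone accounting tables, and a seeded synthetic
    landscape generator so the full pipeline can be exercised without
    external rasters.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    e1071,
    withr,
    optparse
Config/testthat/edition: 3
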