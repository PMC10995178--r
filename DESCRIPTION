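Package: organtrace
Title: Lineage-Based Growth and Differentiation Gradient Analysis for
    Plant Organ Epidermis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies cellular growth from time series of segmented
    epidermal cell layers: per-lineage area expansion, principal growth
    stretches and anisotropy from junction correspondence, directional
    growth decomposed along organ axes via Bezier grids, geodesic
    cell-distance fields on the cell adjacency graph, binned gradient
    profiles, permutation-based gradient statistics, onset-time
    detection, and stomata distributions. Ships a seeded generator of
    growing, dividing, differentiating cell tessellations with
    prescribed growth, anisotropy and differentiation-onset fields so
    that every stage of the pipeline is testable against ground truth
    without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
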