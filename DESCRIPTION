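Package: gldmap
Title: Graph Lesion-Deficit Mapping with Layered Stochastic Block Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps the anatomical substrates of cognitive deficits from
    focal brain lesions by modelling the lesioned brain as a layered
    graph. Parcel-level nodes are joined by edges carrying two weight
    channels, lesion co-occurrence and deficit severity, and community
    structure is inferred by minimum-description-length stochastic block
    modelling, with a behaviour-permuted null graph providing the
    inferential contrast. Includes a synthetic lesion-cohort generator
    (parcellated volumes, region-grown unilateral lesions, deficit
    scores with covariates, item-level reasoning-task responses),
    age-adjusted group statistics with Bonferroni-corrected post hocs,
    bootstrap confidence intervals for backprojected node strengths, and
    a confidence-interval disjointness rule for substrate retention.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    yaml,
    graphics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
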