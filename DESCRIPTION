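Package: rcmstrata
Title: Skin Strata Delineation in Reflectance Confocal Microscopy Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies each slice of a depth-ordered reflectance confocal
    microscopy (RCM) stack as epidermis, dermal-epidermal junction (DEJ)
    or dermis using recurrent convolutional networks over frozen per-slice
    CNN features, including a Toeplitz (local, convex-kernel) attention
    mechanism and a global additive attention variant. Provides an
    anatomical-consistency post-processing heuristic (3-slice median
    filter followed by a causal max filter), boundary-depth extraction in
    micrometers, evaluation metrics (per-class sensitivity/specificity,
    anatomically inconsistent transition counts, boundary mean absolute
    error), and a seeded synthetic stack simulator with known ground
    truth so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tiff,
    png,
    jsonlite,
    data.table,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
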