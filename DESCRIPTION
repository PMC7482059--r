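Package: fermspace
Title: Mass- and Electron-Balance Product Spaces for Gut Fiber Fermentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stoichiometric modeling of prebiotic fiber fermentation by the human
    gut microbiota. Builds elemental (C, H, O) and electron balance matrices for a
    configurable species panel, computes the feasible product polytope for one mole
    of fiber (inulin or pectin) by null-space construction and exhaustive vertex
    enumeration, and queries it by linear programming (per-product maxima, 2D hull
    projections, feasibility of measured profiles, single-input relaxations, fixed
    biomass yields). Companion tools convert ex vivo gas and short-chain fatty acid
    measurements into net mol-product-per-mol-fiber profiles, test paired fiber
    contrasts exactly, ordinate and variance-partition product profiles
    (PCoA/PERMANOVA), associate community taxa with hydrogen yield by lasso
    regression with leave-one-out cross-validation, and simulate seeded synthetic
    communities and measurements for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    pracma,
    stats,
    utils
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
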