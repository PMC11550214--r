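Package: biokin
Title: One-Compartment Biokinetic Modelling of Nanomaterial Bioaccumulation
    in Invertebrates
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Closed-form one-compartment (OC) and one-compartment
    stored-fraction (OC-SF) biokinetic models of contaminant uptake and
    elimination in soil and aquatic invertebrates, with genetic-algorithm
    nonlinear least-squares estimation of the uptake rate constant k1, the
    elimination rate constant k2 and the dimensionless stored fraction SF
    from time-concentration data.  Goodness-of-fit and model selection via
    adjusted R-squared, AICc and Akaike weights; a registry of published
    exposure scenarios for aquatic and soil invertebrates exposed to
    nanomaterials; seeded synthetic-data generation and parameter-recovery
    studies; CSV/JSON input-output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
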