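Package: qsar3d
Title: 3D-QSAR Field Analysis and Conceptual-DFT Reactivity Descriptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for ligand-based three-dimensional quantitative
    structure-activity relationship (3D-QSAR) modelling of congeneric
    small-molecule series, built around comparative molecular field
    analysis (CoMFA) and comparative molecular similarity indices
    analysis (CoMSIA).  Provides rigid maximum-common-substructure
    alignment, Lennard-Jones/Coulomb and Gaussian similarity-index field
    generation on a shared rectilinear grid, partial least squares (PLS)
    regression with leave-one-out cross-validation, field-contribution
    analysis and contour-map export, together with conceptual-DFT global
    reactivity descriptors (chemical potential, hardness, softness,
    electrophilicity) and condensed Fukui functions computed from
    frontier-orbital energies and atomic electron populations.  Ships a
    curated thienopyridine IKK-beta inhibitor activity table and a
    synthetic-data generator for fully reproducible desk-scale analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    igraph,
    ChemmineR,
    methods
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
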