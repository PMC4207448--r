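Package: autogpa
Title: Automated Pharmacophore-Aligned 3D-QSAR Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds 3D-QSAR models from 2D structures and biological
    activities alone. Generates low-strain conformer ensembles, perceives
    pharmacophore feature points, searches for common pharmacophore queries
    that align the training molecules, computes CoMFA-style steric and
    electrostatic grid fields over each aligned ensemble, fits partial
    least squares regressions with leave-one-out cross-validation, and
    ranks the resulting pharmacophore + field models by q-squared. New
    molecules are predicted by aligning their conformers onto a saved
    query and taking the maximum predicted activity over conformers.
License: MIT
Encoding: UTF-8
Imports:
    ChemmineR,
    bio3d,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
SystemRequirements: OpenBabel 3.x (obabel and obenergy on the PATH)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
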