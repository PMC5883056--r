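Package: cxqsar
Title: 2D-QSAR Modeling, Validation and Virtual Screening for Caged
    Xanthone Anticancer Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds, validates and applies 2D quantitative
    structure-activity relationship (QSAR) models of caged-xanthone
    anticancer activity against the A549, HepG2 and U251 cell lines.
    Computes electrotopological-state (E-state) indices, topological
    atom-pair counts and related 2D descriptors from SMILES; rebuilds
    models by sphere-exclusion train/test splitting and stepwise-forward
    multiple linear regression; runs a twelve-item statistical validation
    battery (LOO q2, external pred_r2, rm2 metrics, Y-randomization,
    applicability domain); ships the three published cell-line equations
    as frozen scorers; and screens compound libraries through a
    predicted-activity cutoff, Lipinski's rule of five and a configurable
    risk-rule stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
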