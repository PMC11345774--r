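Package: kappascreen
Title: Pharmacophore and Gaussian-Shape Virtual Screening for Nonbasic KOR Agonist Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An open, tested re-implementation of a ligand-based virtual-screening
    workflow for discovering nonbasic kappa-opioid receptor (KOR) agonists seeded by
    the Salvinorin A pharmacophore. Provides 3D pharmacophore feature perception and
    rigid-body query matching with exclusion volumes, first-order Gaussian shape
    overlay with shape/color Tanimoto scoring, DUD-E-style property-matched decoy
    generation, ROC/AUC/enrichment validation statistics, and a hit-triage stage with
    charge/basicity and physicochemical filters, fixed-frame pharmacophore re-scoring
    of docking poses, and receptor-contact annotation. A synthetic-data module builds
    every input the pipeline needs, deterministically under a seed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
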