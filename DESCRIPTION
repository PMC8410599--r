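Package: orpharm
Title: Olfactory Receptor Pharmacology from Calcium-Indicator Plate Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deorphanizing olfactory receptors with cell-based
    calcium-indicator (GCaMP) plate-reader assays. Converts raw well
    fluorescence traces into baseline-normalized responses (deltaF/F),
    normalizes them to per-plate positive and negative controls, fits Hill
    dose-response curves with a censoring convention for non-saturating
    ligands, and summarizes agonism with an activity index combining
    apparent affinity and efficacy. Receptor tuning breadth is quantified
    with lifetime sparseness, mutants are compared to wild type with
    ANOVA/Dunnett or Brown-Forsythe test-selection logic, and exhaustive
    one- and two-descriptor linear regressions rank which physicochemical
    properties of a ligand panel predict agonism. A plate simulator with
    known ground truth exercises the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    minpack.lm,
    multcomp,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
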