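Package: fvforge
Title: Antibody Variable-Region Structure Prediction, Evaluation and Curation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of an antibody Fv structure-prediction
    stack: rigid-frame geometry and Kabsch superposition, an eight-block
    structure module built from invariant point attention and quaternion
    backbone updates, region-clamped frame-aligned point error (FAPE), torsion
    and structural-violation training losses, a 50-bin pLDDT confidence head,
    per-residue lDDT-CA and chain-aligned per-region RMSD evaluation, and a
    deterministic SAbDab-style curation pipeline. Every component is
    exercisable on seeded synthetic antibody-like fixtures, so no external
    data or model download is required. Includes a reverse-mode automatic
    differentiation tape and a two-stage training harness (RAdam with
    cosine-annealing warm restarts) runnable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    bio3d,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
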