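Package: collagenHier
Title: Hierarchical Collagen Organization from Fiber Diffraction and
    Polarization-Resolved Second Harmonic Generation
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reduction and analysis of dual-modality measurements of
    collagen hierarchical organization in mineralizing tendon. Reduces
    small-angle fiber-diffraction scatter patterns to five structural
    metrics (collagen D-period, intermolecular spacing, fibril and
    molecular azimuthal dispersions, relative supramolecular twist) via
    azimuthal integration, Porod background subtraction and per-segment
    orientation profiling; fits the circular-harmonic polarization model
    to polarization-resolved second harmonic generation (pSHG) image
    stacks to map the organization parameter I2 and dominant orientation
    phi2; and compares non-mineralizing, early- and late-mineralizing
    tendon regions with one-way ANOVA and Tukey-Kramer post hoc tests.
    Includes synthetic scatter-pattern and pSHG-stack generators with
    known ground truth so the full pipeline is testable without beamline
    or microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    jsonlite,
    yaml,
    tiff,
    minpack.lm,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'geometry.R'
    'synthetic-scatter.R'
    'synthetic-pshg.R'
    'xrd-reduction.R'
    'pshg-analysis.R'
    'stats-compare.R'
    'io.R'
    'pipeline.R'
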