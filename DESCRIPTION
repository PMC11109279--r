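Package: heliomod
Title: Operon Neighborhood, Residue Conservation, and Binding/Kinetic
    Analysis for Heliorhodopsin-Modulated Transporters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying heliorhodopsins (HeRs) that modulate
    neighboring proteins encoded in the same operon. Implements
    gene-neighborhood extraction and co-transcription prediction from
    annotated genomes (intergenic-distance and strand heuristic),
    classification of HeR anchors into neighbor-gene groups, reference-
    anchored alignment-column amino-acid frequency profiles with
    differential-enrichment flagging and intracellular-loop charge
    conservation, isothermal titration calorimetry isotherm models
    (one-site Wiseman and two-step sequential binding) with nonlinear
    least-squares fitting and derived thermodynamics (Kd, dH, -TdS, dG),
    and the companion kinetic calculations: Michaelis-Menten fits with
    kcat and specificity constants, four-parameter logistic dose-response
    with IC50, exponential decay with half-life, Henderson-Hasselbalch
    pKa, inorganic-phosphate calibration, MIC80, and fluorescence-trace
    normalization. Seeded synthetic-data generators with planted ground
    truth make every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
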