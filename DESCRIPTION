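Package: synmorph
Title: Nanoscale Synaptic Morphology and Point-Pattern Analysis for
    Expansion Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for quantitative analysis of
    expansion-microscopy (ExM) and ExM-STED imaging of synapses: validation
    of comparable local expansion from active-zone to postsynaptic-density
    (AZ-PSD) line profiles, 3D shape fingerprinting of postsynaptic
    scaffolds (nine-feature descriptors, PCA, CLARA clustering with
    Gap-statistic model selection, principal-curve pseudotime), 2D
    subsynaptic particle detection and spatial point-pattern statistics
    (nearest-neighbour distances, Ripley's K, Manders colocalization,
    overlap-pair distances), and the accompanying statistical layer
    (semi-parametric MANOVA with the modified ANOVA-type statistic and
    parametric bootstrap, chi-square composition tests, repeated-measures
    ANOVA, rank-sum tests, multiplicity corrections). A seeded synthetic
    data generator emulates all input data kinds with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    cluster,
    MASS,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
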