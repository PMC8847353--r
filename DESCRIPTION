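Package: patquant
Title: Quantitative Comparison of Photoacoustic Tomography Contrast with
    Light-Sheet Virtual Histology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for assessing photoacoustic tomography (PAT) tissue
    contrast against three-dimensional light-sheet virtual histology in
    breast biopsy volumes. Implements channel binarization (Otsu for PAT,
    region-averaged histogram thresholds for fluorescence channels),
    composition-positive pixel maps over three-slice analysis regions,
    regional percent composition, ordinal 1-3 scoring of cancerous and
    non-cancerous regions of interest under separate vascular/lipid and
    nuclei rubrics, rank-based ROC AUC, and the accompanying statistical
    battery (linear regression, Shapiro-Wilk gated transforms, one-way
    ANOVA with Tukey HSD, Kruskal-Wallis with Dunn post-hoc tests). A
    seeded synthetic-phantom generator produces co-registered multimodal
    biopsy volumes (PAT lipid/hemoglobin/off-resonance, ultrasound, and
    eosin/DRAQ5 light-sheet channels) with known ground truth so the
    entire pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    tiff,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'methods-accessors.R'
    'phantom.R'
    'volume-io.R'
    'preprocess.R'
    'thresholding.R'
    'composition.R'
    'roi-scoring.R'
    'stats.R'
    'virtual-he.R'
    'pipeline.R'
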