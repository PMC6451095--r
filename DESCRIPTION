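Package: FociTrace
Title: Single-Molecule Focus Quantification and Binding Kinetics for
    Live-Cell Bacterial Fluorescence Microscopy
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies DNA-bound single-molecule fluorescent fusion
    proteins in rod-shaped bacteria from time-lapse and burst-acquisition
    imaging. Provides focus detection inside cell outlines with per-cell
    statistics, photobleaching-step calibration of the single-molecule
    intensity unit, copy-number and concentration estimation with
    autofluorescence correction, directional two-channel colocalization
    with an analytic chance baseline, autocorrelation decomposition of
    focus-intensity trajectories into short/medium/long components, and
    short-axis (cell width) localization profiles. A synthetic-microscopy
    generator and a stochastic binding/bleaching trajectory simulator
    supply ground-truthed inputs so the full pipeline is testable without
    real data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    EBImage,
    tiff,
    mgcv,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: SingleCell, CellBiology, Visualization, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'FociTrace-package.R'
    'accessors.R'
    'colocalization.R'
    'detection.R'
    'io.R'
    'kinetics.R'
    'pipeline.R'
    'render.R'
    'spatial.R'
    'stoichiometry.R'
    'synthetic-cells.R'
    'trajectory-sim.R'
    'utils.R'
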