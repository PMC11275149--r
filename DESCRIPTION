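Package: dynPET
Title: Dynamic FDG-PET/MR Quantification for Preclinical Tumor Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Kinetic quantification of dynamic [18F]FDG PET in small-animal
    tumor models: time-activity curve extraction from 4-D volumes,
    image-derived plasma input functions built from vena-cava and liver
    curves, Patlak graphical estimation of the net influx rate Ki, metabolic
    rate of glucose and SUV-family uptake metrics, and log-linear
    tumor-growth (doubling-time) analysis. Includes a two-tissue-compartment
    phantom simulator (Feng-type plasma input, plasma-to-blood ratio model,
    voxelized organ phantoms, lognormal growth cohorts) so the whole
    pipeline is testable end to end without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    deSolve
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'frame-schedule.R'
    'imaging-io.R'
    'synthetic-input.R'
    'synthetic-tissue.R'
    'phantom.R'
    'growth-sim.R'
    'tac.R'
    'metabolic.R'
    'uptake.R'
    'input-function.R'
    'patlak.R'
    'growth-analysis.R'
    'study-analysis.R'
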