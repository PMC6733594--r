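Package: phresh
Title: Simulation and Quantification of Photoconvertible Reporter Signalling
    Histories
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for photoconversion-based signalling-history (PHRESH)
    analysis of dual-channel Kaede reporter imaging in the zebrafish spinal
    cord. Provides a synthetic-embryo generator with ground-truth Notch and
    Hedgehog activity fields over the three phases of spinal-cord signalling
    dynamics, a green/red Kaede kinetics simulator with instantaneous
    photoconversion, a two-channel confocal stack renderer with transverse
    reslicing, the PHRESH measurement chain (unconverted-reference
    normalization, dorsoventral and mediolateral intensity profiles,
    response-state classification, spatiotemporal maps), expression-domain
    morphometry with control-maximum normalization, and Mann-Whitney U group
    comparison with significance annotation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    tools,
    tiff,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Software, CellBiology, Visualization, Spatial
RoxygenNote: 7.3.3
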