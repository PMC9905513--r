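Package: artefactscan
Title: Image-Based Condition Survey Tools for Paintings
Version: 0.1.0
Authors@R:
    person("artefactscan", "maintainers", email = "maintainers@artefactscan.org",
           role = c("aut", "cre"))
Description: Toolkit for minimally invasive condition surveys of paintings.
    Locates probable biodeterioration areas in large ultraviolet-fluorescence
    photographs by correlation-coefficient template matching, with threshold
    sweep/selection, grouped detections mapped to a sampling grid, and a
    sampling-efficiency report. Quantifies pigment-crystal arrangement in tiled
    cross-section micrograph mosaics: colour-class segmentation, overlap-aware
    deduplication across tiles, and same-/cross-colour inter-crystal distance
    statistics with histograms. Includes seeded synthetic-fixture generators
    (scenes with planted templates, crystal mosaics with ground truth, station
    logs) and light environmental summaries (diurnal extrema, volumetric
    aerial spore concentration).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
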