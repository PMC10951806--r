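Package: mxpcf
Title: Extended Correlation Functions for Marked Spatial Point Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Spatial statistics for cell-centroid data from multiplex
    imaging, treated as marked point patterns on a rectangular domain.
    Implements the pair correlation function (PCF) and cross-PCF with
    annulus-area edge correction, topographical correlation maps (TCM)
    built from linearized per-cell local correlations, neighbourhood
    correlation functions (NCF) based on minimum enclosing circles of
    k-type tuples, and weighted PCFs (wPCF) for continuous marks such as
    stain intensities. Includes synthetic point-pattern generators,
    complete-spatial-randomness simulation envelopes, pixel-lattice
    sampling of intensity rasters for segmentation-free analysis, and
    cell-table CSV input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
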