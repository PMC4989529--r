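Package: hsseg
Title: Dedicated Segmentation Methods for Hyperspectral Image Cubes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segmentation of hyperspectral image cubes with three methods
    profiled to spectral data: fast per-pixel matching of emissivity curves
    against a reference waveform, whole-sequence 3D segmentation from a
    region-of-interest reference with volumetric median filtering, and
    hierarchical segmentation at reduced resolution with unsupervised
    class-count selection and conditional morphological stabilization of
    per-band masks.  Includes raw BIL/BSQ cube input and output with
    ENVI-style sidecar headers and fast partial-row reads, 3D and
    band-adaptive median denoising, dark/white reflectance calibration,
    confusion-matrix evaluation (sensitivity, specificity, balanced
    accuracy), and a synthetic phantom generator with known ground truth,
    band-edge-amplified noise and small artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    graphics,
    grDevices,
    jsonlite,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
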