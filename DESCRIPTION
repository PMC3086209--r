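Package: microrad
Title: Quantitative Contact X-Ray Microradiography of Dental Hard Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying enamel erosion and demineralization from
    digitized contact x-ray microradiographs. Provides uncompressed grayscale
    TIFF input/output preserving 8/12/16-bit depth, spatial calibration from
    stage-micrometer counts, aluminum step-wedge film-linearity assessment
    with two-point (20%/80%) grayscale normalization, width-averaged density
    profile extraction, before/after profile registration on metal-grid
    fiducial peaks, two-point (background 0% / sound enamel 100%) mineral
    density normalization, and geometric measurement of erosion depth and
    demineralization lesion depth. A synthetic phantom generator emulates
    negative-polarity film radiographs of thin tooth slabs with a grid
    fiducial, a step wedge, film-response nonlinearity at scale extremes,
    per-radiograph brightness/contrast variation and grain noise, providing
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
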