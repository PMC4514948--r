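Package: syndesmo3d
Title: Automated 3-D CT Morphometry of the Distal Tibiofibular Syndesmosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the normal distal tibiofibular syndesmosis on CT-like
    volumes and triangulated bone surfaces. Segments bone by Hounsfield
    thresholding with small-component removal, fits the tibial plafond plane,
    constructs the individualized measurement plane through the lateral
    prominence of the anterior tubercle, and computes the tibiofibular clear
    spaces (TCS-A, TCS-P), incisura depth and height (IFD, IFH), plane height
    (XY) and radiographic tibiofibular overlap (TFO) in 3-D, 2-D axial and
    simulated anteroposterior-radiograph modalities. Includes a parametric
    ankle phantom generator with analytically known ground truth, a simulated
    rater-table generator, and the reliability statistics used to validate the
    measurements: ICC(2,1) absolute agreement with exact F-based confidence
    intervals, RMS-SD precision, ANCOVA with body height as covariate, and
    paired t tests across modalities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    igraph,
    jsonlite,
    purrr,
    RNifti,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
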