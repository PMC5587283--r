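Package: diamorph
Title: Regional Morphometry of Striated Muscle from Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies the microstructure of striated muscle (diaphragm) from
    confocal fluorescence images: modal sarcomere length by band-pass-filtered
    2D FFT, interstitial-space ratio and branched-fiber percentage from
    longitudinal whole-mount images, and fiber cross-sectional area, centrally
    nucleated (regenerating) fiber percentage and CD68+ macrophage density from
    immunostained cross-sections. Includes a seeded synthetic-image and cohort
    generator with exact ground truth for validation, a Holm-Sidak step-down
    multiple-comparison engine over genotype x age x region designs, and a
    reproducible generate-measure-compare pipeline with manifest tracking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    withr,
    tibble,
    dplyr,
    readr,
    ggplot2,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
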