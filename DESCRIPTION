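Package: siribruise
Title: Structured-Illumination Reflectance Imaging Analysis for Subsurface Bruise Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting subsurface bruises in fruit with
    structured-illumination reflectance imaging (SIRI). Renders
    phase-shifted sinusoidal pattern images of ground-truthed fruit
    phantoms, demodulates them into DC, AC and ratio (RT) images by
    three-phase demodulation, selects the operating spatial frequency
    with a contrast index over a frequency sweep, extracts
    gray-level co-occurrence matrix (GLCM) Haralick texture features,
    selects features with the random-frog algorithm scored by
    cross-validated PLS-DA, and classifies sound versus bruised samples
    with least-squares SVM, PLS-DA and k-nearest-neighbour models under
    a repeated stratified-split evaluation protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
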