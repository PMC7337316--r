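Package: leafmetrics
Title: Leaf Length and Width Measurement from Photographs of Leaves on a
    Reference Sheet
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@leafmetrics.org",
           role = c("aut", "cre"))
Description: Measures the length and width of a detached plant leaf from an
    RGB photograph of the leaf lying on a white rectangular reference sheet of
    known physical size. The pipeline segments the leaf by blue-channel
    histogram-valley thresholding, removes perspective distortion by
    rectifying the sheet's four corners with an exact four-point homography,
    de-skews the leaf using the straight basal portion of the midrib, locates
    the leaf tip and petiole insertion on the traced boundary (handling both
    convex and concave/notched extremities via a difference-curve peak
    search), and converts pixel measurements to centimetres using the sheet
    as a calibration target. Includes a ground-truthed synthetic scene
    generator for validation, and paired-error statistics (MAE, RMSE,
    accuracy rate) with broom-style tidiers and ggplot2 diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    generics,
    ggplot2,
    grDevices,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    jpeg,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
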