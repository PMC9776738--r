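Package: priorgrow
Title: Automatic Lung Tumor Segmentation by Prior-Guided Seeded Region
    Growing
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Automatic segmentation of lung tumors in single 2-D CT
    slices.  A tumor candidate is localized without user interaction by
    Otsu binarization of a contrast-adjusted slice, contour extraction,
    and a prior-knowledge filter on physical size (maximum diameter in
    (2, 5] cm) and area (in (1, 6.25*pi] cm^2) taken from TNM staging
    cut-points; the candidate's centroid seeds a seven-point ensemble of
    queue-based region growers whose gray-level tolerance is updated
    automatically from each previous result, with growth-restriction
    credibility checks guarding against leakage.  The union of credible
    grown regions is the final segmentation.  Includes Dice and Jaccard
    evaluation, a synthetic lung-slice phantom generator with ground
    truth for validation, and readers for DICOM, PNG and TIFF slices
    with physical pixel spacing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
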