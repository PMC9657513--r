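Package: thermolesion
Title: Thermographic Segmentation and Longitudinal Monitoring of Infantile Hemangiomas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for radiometric thermal images of cutaneous
    vascular lesions, in particular infantile hemangiomas. Reads and calibrates
    thermal frames, segments skin from the scene background by Otsu
    thresholding of the temperature histogram, extracts isotherm contour lines
    by marching squares, computes lesion areas in pixel and physical units via
    the shoelace (coordinate) method and a pinhole projection model, measures
    the temperature difference between the lesion core and the surrounding
    healthy skin, and classifies longitudinal treatment response with
    rule-based agreement criteria. A synthetic thermal-phantom generator with
    analytic ground truth makes every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
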