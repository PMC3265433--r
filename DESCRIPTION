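Package: spinealign
Title: Frontal-Plane Spinal Alignment Analysis for Sleep-Surface Ergonomics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies frontal-plane spinal alignment of a person lying
    laterally on a mattress, from surface-marker coordinates on twelve
    vertebrae (C7-L5). Provides the P8 kink angle between total-least-squares
    lines fitted to the thoracic and lumbar marker segments and its
    deviation-from-straight statistic (180 - P8); marker-centre detection in
    grayscale images; LGA load-deflection stiffness metrics (E, C, E/C) with
    surface-class lookup; a quasi-static model of a segmented body on a zoned
    elastic mattress with zonal-stiffness customization that straightens the
    simulated spine; heteroscedastic group comparison (Welch ANOVA, Levene,
    Tamhane T2 post hoc); and a synthetic cohort generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    car,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
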