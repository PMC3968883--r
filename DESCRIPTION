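Package: femsym
Title: Bilateral Symmetry Analysis of Proximal Femur Shape from 2D Landmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical shape modelling of paired left-right proximal femur
    contours from calibrated 2D landmark sets. Builds point distribution
    models via generalized Procrustes alignment and principal component
    analysis, identifies oppositional-asymmetric modes of a combined
    left-right model that are attributable to subject positioning during
    radiograph acquisition, removes them and re-evaluates landmark
    positions, quantifies left-right shape symmetry by mean point-to-curve
    distance and per-mode Welch tests, and derives conventional hip
    geometric measurements (head diameter, neck width, shaft width,
    neck-shaft angle) together with absolute-percent-asymmetry statistics.
    Includes a seeded synthetic landmark generator emulating shared
    bilateral anatomy, mirror correspondence, positioning artefacts and
    measurement noise, plus an end-to-end analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
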