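Package: hydroffr
Title: Hydrostatic Pressure Correction of Intracoronary Pressure Indices
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies and corrects the effect of hydrostatic pressure on
    invasive coronary pressure indices. Extracts orifice-to-sensor height
    differences from 3D coronary centerlines (direct coordinate difference,
    foreshortening-corrected chord triangle, or 2D lateral projection),
    converts heights to hydrostatic pressure offsets (0.077 mmHg per mm of
    blood column), corrects fractional flow reserve (FFR) and resting Pd/Pa,
    builds per-segment correction tables over the Syntax coronary
    nomenclature, performs cutoff-based reclassification analysis, and
    generates synthetic cohorts for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
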