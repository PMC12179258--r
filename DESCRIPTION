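Package: skintone
Title: Automated Skin Tone Assessment from Images via the Individual Typology Angle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automatic skin tone quantification for dermatological
    image analysis. Converts sRGB pixels to CIELAB, computes the Individual
    Typology Angle (ITA) over anatomically defined regions (lower arms from
    body-part label maps, the nasal bridge from 68-point facial landmarks),
    calibrates ITA class boundaries for the Monk Skin Tone Scale from its
    reference palette, classifies on the Monk and Fitzpatrick scales, and
    evaluates classification quality with tolerance-margin accuracy,
    balanced accuracy, Fleiss' kappa and Mann-Whitney subgroup comparisons.
    Includes a seeded synthetic-image generator with known colorimetric
    ground truth, so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    farver,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
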