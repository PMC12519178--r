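Package: ivcfit
Title: Circle-Fitting Prediction of Inferior Vena Cava Diameter After Filter Placement
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Predicts the inferior vena cava (IVC) diameter after vena cava
    filter placement from pre-placement maximum and minimum diameters using a
    circle-fitting model: the oval cross-section's circumference is
    approximated with Ramanujan's formula and converted to the equivalent
    circular diameter. Includes the concordance-based validation machinery
    (Lin's concordance correlation coefficient with asymptotic confidence
    intervals, agreement classification, bootstrap comparison of dependent
    CCCs, Student's t tests), a synthetic cohort simulator emulating the
    oval-to-circular post-placement remodeling, and a CSV-to-JSON analysis
    pipeline with a thin command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
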