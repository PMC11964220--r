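Package: maizeNrec
Title: Image-Based In-Season Nitrogen Prescription and Nitrogen-Use
    Accounting for Maize
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Turns leaf photographs into in-season fertilizer nitrogen
    prescriptions for maize. Computes the dark green colour index (DGCI)
    from RGB images via hue/saturation/brightness, combines it with
    thermal time (growing degree days) into the in-season estimated
    yield (INSEY), fits the power-law yield-potential calibration,
    applies the response-index dose equation, and optionally runs the
    same pipeline on NDVI readings. Also provides the agronomic
    evaluation metrics used to validate sensor-based nitrogen
    management: growth indices, nitrogen-use-efficiency indices
    (physiological efficiency, partial nitrogen balance, internal
    utilization efficiency, virtual nitrogen factor), greenhouse-gas
    intensity, energy accounting and eco-efficiency indices, together
    with synthetic-data generators for leaf images, weather series,
    calibration trials and validation plot tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jpeg,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
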