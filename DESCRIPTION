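Package: isomilk
Title: Stable-Isotope Verification of Milk Provenance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for verifying the geographic provenance of cow milk from
    paired oxygen and hydrogen stable-isotope measurements of milk water and
    farm (drinking) water. Implements the milk/farm-water fractionation
    factor, deuterium excess, dual-isotope water-line and seasonal quartic
    calibrations with prediction bands, a two-step compatibility check with
    propagated measurement uncertainty (developed for the
    Parmigiano-Reggiano production region), and a synthetic dairy-herd
    generator for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
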