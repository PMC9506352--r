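Package: pawsig
Title: Quantification of Plasma-Activated Water Induced Calcium Signatures
    from Aequorin Luminescence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis chain for plant aequorin bioluminescence assays of
    plasma-activated water (PAW): forward simulation of photon-counting
    plate runs from ground-truth cytosolic calcium trajectories, calibration
    of luminescence to molar calcium via the aequorin rate-constant curve,
    extraction of calcium-signature metrics (peak, onset delay, rise slope,
    integrated dynamics) for single- and two-dose protocols, a first-order
    heat-transport model fitted to water-temperature series to obtain the
    transferred energy per unit mass used as the PAW dose, pairwise Student
    t tests with compact letter displays, and dose-response aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    deSolve,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
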