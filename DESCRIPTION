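Package: volePOM
Title: Individual-Based Field Vole Population Model with Pattern-Oriented Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An individual-based model of field vole (Microtus agrestis)
    population dynamics on 1 m resolution raster landscapes, with daily
    time steps, explicit territory acquisition and eviction, dispersal
    mortality, infanticide, weather-driven breeding phenology, and an
    optional specialist predator layer generating multi-annual population
    cycles. Includes a virtual-ecologist live-trapping module, pattern
    statistics for age/sex structure, habitat-specific densities, natal
    and adult dispersal, and cycle metrics, together with a sequential
    pattern-oriented calibration engine and one-at-a-time sensitivity
    analysis. Scenario landscapes, daily weather series and parameter
    files are generated programmatically for fully reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
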