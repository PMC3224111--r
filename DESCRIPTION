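Package: ureocol
Title: Reactive Transport Modeling of Ureolytically Driven Calcium
    Carbonate Precipitation in Sediment Columns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates enzymatic urea hydrolysis, nitrification,
    calcite-strontianite solid-solution precipitation, Gapon-convention
    cation exchange, and 1D advective transport in a laboratory sediment
    column. Includes an equilibrium carbonate-system speciation solver
    with extended Debye-Hueckel activity corrections, derived observables
    (hydraulic metrics, precipitate mass balances, effluent summaries,
    complex-conductivity decomposition), a least-squares calibrator for
    the kinetic and exchange parameters, and a synthetic effluent-record
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
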