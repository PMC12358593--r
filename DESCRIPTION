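Package: hygrosorb
Title: Moisture Sorption Isotherm Fitting and Sorption Thermodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits moisture sorption isotherms (GAB, Peleg, Smith, Halsey,
    Henderson) and hygroscopic kinetic models (zero-, first-, second-order,
    biexponential) to equilibrium moisture and moisture-gain data by
    multi-start nonlinear least squares, selects the best model by R2/RSS,
    and derives the differential thermodynamic quantities of water sorption:
    Gibbs free energy, net isosteric heat via Clausius-Clapeyron, differential
    entropy, spreading pressure from GAB constants, and enthalpy-entropy
    compensation with isokinetic-temperature classification. Includes a
    seeded synthetic-data generator that emulates a saturated-salt-solution
    isotherm study for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
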