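Package: nflow
Title: Urban Nitrogen Flow Accounting with Uncertainty and Driver Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Substance flow analysis of reactive nitrogen in coupled
    human-natural urban systems. Provides a twelve-subsystem mass-balance
    flux network with a conservation ledger, a declarative activity-by-factor
    flux engine with strict unit handling, Monte Carlo propagation of graded
    input uncertainty (reliability classes mapped to coefficients of
    variation), life-cycle nitrogen-fate indicators (fate fractions, nitrogen
    use efficiency, excreta recycling ratios, environmental load series), and
    an extended STIRPAT ln-linear driver decomposition with effect
    coefficients and contribution rates. Includes a synthetic-city scenario
    generator and a worked fixture of published city-scale fluxes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    lmtest
Config/testthat/edition: 3
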