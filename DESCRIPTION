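Package: mixocarb
Title: Carbon and Electron Balances for Mixotrophic Syngas Fermentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of mixotrophic inorganic carbon capture in
    solventogenic Clostridia from fermentation off-gas and liquid-phase data:
    degree-of-reduction (available-electron) and C-mol carbon balances,
    off-gas molar flow conversion with Henry's-law solubility correction,
    chemostat steady-state detection under the three-residence-time rule,
    detection of synchronous H2/CO2 oscillations, nitrite-pulse electron-sink
    stoichiometry by dose-response regression, and a conservation-enforcing
    synthetic fermentation-data generator so the whole chain is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
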