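Package: epictrl
Title: Rational Social Distancing and Costly Government Intervention in
    SIR Epidemics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Hierarchical optimal-control framework for epidemics with
    endogenous social distancing. Couples a rescaled SIR model to rational
    individual behaviour (a mean-field-game Nash equilibrium computed via
    Pontryagin costates and a forward-backward sweep), the fully coordinated
    utilitarian optimum, and a nested Stackelberg optimization of a
    time-varying government incentive field that is itself costly. Includes
    healthcare-capacity-threshold infection costs, branch continuation across
    the resulting discontinuous policy switch, independent direct-transcription
    oracles, scenario presets, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
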