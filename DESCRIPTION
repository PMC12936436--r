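Package: senesce
Title: Selection on Senescence Rate Under Gompertz-Makeham Mortality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the evolution of senescence when genes act on
    the shape of a Gompertz-Makeham mortality schedule from birth rather than
    at a fixed age of onset. Provides the hazard, survival and certain-mortality
    age of the Gompertz-Makeham model; two fitness estimators (the Euler-Lotka
    intrinsic growth rate and lifetime reproductive success) under four
    density-dependence regimes; closed-form selection gradients on senescence
    rate with their negligible-senescence limits and finite-difference cross
    checks; second- and mixed-derivative evolutionary feedback maps over
    parameter grids; an evolutionarily stable senescence rate under a
    senescence-reproduction trade-off, including brute-force fitting of the
    trade-off shape; nonlinear least-squares calibration of Gompertz-Makeham
    parameters from life tables; and a synthetic life-table generator with
    known truth for parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
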