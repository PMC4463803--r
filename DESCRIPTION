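Package: wheatsens
Title: Global Sensitivity Analysis of a Reduced-Order Wheat Growth and Quality Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A daily-time-step, reduced-order simulator of wheat growth,
    nitrogen economy and grain protein, driven by 75 named morpho-physiological
    trait parameters, together with from-scratch Morris elementary-effects
    screening and extended-FAST variance-based sensitivity analysis. A
    stochastic weather generator emulates three contrasted European climates
    (Mediterranean, Continental, Oceanic) so that trait rankings for grain
    yield, grain protein concentration and grain protein deviation can be
    explored across sites, nitrogen treatments and weather years.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
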