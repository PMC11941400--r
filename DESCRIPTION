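Package: spikemap
Title: Spike-Train Generation and Criticality Analysis with Coupled
    Intermittent Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates neuronal-type spike trains by threshold-coupling a
    critical (type-I) intermittency map with a tricritical intermittency
    map, so that upward bursts of the first map trigger the spike fall of
    the second and vice versa.  Provides the accompanying analysis stack:
    laminar-length extraction within a value band, the method of critical
    fluctuations (scan of the upper band edge until the exponential
    correction of a truncated power-law fit vanishes), truncated
    power-law fitting with confidence intervals, inter-spike-interval
    distributions, and the critical-exponent relations linking the map
    exponents to the isothermal critical exponent.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
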