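Package: pppflux
Title: Pentose Phosphate Pathway Flux Analysis from 1,2-13C2 Glucose Tracing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating pentose phosphate pathway (PPP) branch
    fluxes from 1,2-13C2 glucose stable-isotope tracing time courses.
    Provides mass-isotopologue distribution (MID) handling with
    normalisation and natural-abundance correction, a forward simulator of
    label propagation through glycolysis and the oxidative and
    non-oxidative PPP branches, dilution-rate (turnover) estimation from
    isotopologue accumulation curves with the continuous stirred-tank
    reactor (CSTR) model via least-squares Monte Carlo, and empirical
    one-sided p-values for treatment-versus-control flux differences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    deSolve,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
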