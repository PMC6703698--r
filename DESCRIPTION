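Package: equihemo
Title: One-Dimensional Pulse Wave Propagation Model of the Equine Arterial
    Circulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates pressure and flow wave propagation through a
    117-segment model of the equine arterial tree.  The area-averaged
    continuity and momentum equations are solved with an implicit
    second-order finite-difference scheme over a bifurcating network of
    tapered elastic segments, coupled proximally to a four-phase
    time-varying elastance left ventricle and distally to three-element
    Windkessel terminal loads, with Witzig-Womersley oscillatory-flow
    theory supplying wall friction and convective-acceleration
    corrections and an optional gravitational body force for the standing
    animal.  Post-processing includes cardiac output, ejection fraction,
    regional flow distribution, foot-to-foot pulse wave velocity and
    forward/backward wave power decomposition.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
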