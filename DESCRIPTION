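Package: conjphage
Title: Kinetics of Competition Between Bacterial Conjugation and M13 Phage
    Infection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and calibrates a resource-limited compartmental model
    of F-plasmid conjugation competing with filamentous M13 phage infection
    in Escherichia coli batch culture. Provides the full nine-variable ODE
    system and its conjugation-only and infection-only reductions with
    Monod-type (hyperbolic) rate laws, presets for the standard flask
    inoculation conditions, a synthetic qPCR time-series generator for the
    tolC, traI and M13 marker loci with threshold-cycle (Ct) noise, a staged
    least-squares parameter-estimation procedure that recovers growth,
    conjugation, infection and penalty parameters from marker time series,
    and derived metrics such as the conjugation-to-infection encounter-rate
    ratio and phages-per-cell burden.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
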