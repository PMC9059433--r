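Package: ventsim
Title: Desk-Scale Simulation of the Breathable-Air Circuit of a
    Volume-Controlled Electro-Pneumatic Ventilator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the breathable-air circuit of an electro-pneumatic
    volume-controlled ventilator (VCV) at desk scale: compressible orifice
    flow through solenoid gating valves with choked and subsonic regimes,
    coupled isothermal pressure dynamics of a rigid patient tube and a
    single-compartment compliant lung, a piecewise volume-cutoff flow
    controller, and the relay-ladder switching logic of 5/2, 5/3 and 3/2
    solenoid-valve circuits with on-delay timers. Produces tidy waveform
    tables and per-breath metrics (peak pressure, plateau, PEEP, delivered
    volume, peak expiratory flow), parametric sweep tooling over tidal
    volume and exhaust time, ggplot2 visualisations, and a small command
    line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
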