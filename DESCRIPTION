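Package: csfshunt
Title: Lumped-Parameter Electrical-Analog Simulation of CSF Dynamics and
    Hydrocephalus Shunting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the production, circulation and absorption of
    cerebrospinal fluid (CSF) as a pulsatile-pressure-driven
    resistor-capacitor-diode network, in the tradition of the
    Marmarou/Ursino lumped-parameter models of intracranial pressure (ICP)
    dynamics. Hydrocephalus is represented by an elevated CSF outflow
    resistance and a shunt by a low resistance in series with a one-way
    valve. Provides a stiff ODE simulator with an analytic DC steady-state
    oracle, scenario runners for normal, moderate and severe hydrocephalus
    and for constant, blocked and time-varying shunts, shunt-efficiency and
    percent-increase metrics, Poiseuille catheter-geometry resistance
    mapping, and design tools that solve for the shunt resistance achieving
    a target efficiency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
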