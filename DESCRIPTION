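Package: sensillum
Title: Compartmental Electrical Model of the Moth Pheromone-Sensitive
    Sensillum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the receptor potential (RP) and tip-recorded
    sensillar potential (SP) of a moth pheromone-sensitive olfactory
    receptor neuron inside its sensillum. The outer dendrite is
    discretized into N isopotential compartments carrying Hill-gated,
    pheromone-dependent ionic conductances (IP3-gated Ca2+, DAG-gated
    cationic, Ca2+-gated Cl-, Na+/Ca2+ exchange) with feedback
    inhibition, coupled through sensillar-lymph and intracellular axial
    conductances to a lumped inner-dendrite/soma compartment (leak and
    Ca2+/voltage-gated K+ currents) and a lumped auxiliary-cell
    compartment generating the transepithelial potential. A simplified
    single-conductance variant, closed-form steady-state cable solutions
    and a small-signal eigenfunction transient solution serve as
    analytic oracles. Includes dose-response characterization (height,
    half-rise, half-fall, EC50), parameter sweeps, and Nelder-Mead
    fitting of response characteristics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
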