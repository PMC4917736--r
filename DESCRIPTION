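Package: nicesim
Title: Cell-Type-Selective Ultrasonic Neuromodulation of Hodgkin-Huxley Neuron Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates ultrasonic neuromodulation by representing pulsed
    ultrasound as a carrier-frequency modulation of membrane capacitance
    (the NICE framework's sinusoidal reduction) driving single-compartment
    Hodgkin-Huxley models of five mammalian neuron types (regular-spiking,
    fast-spiking and low-threshold-spiking cortical neurons; thalamocortical
    and thalamic reticular neurons) and a three-population cortical
    microcircuit with dynamic AMPA/GABA-A synapses and short-term plasticity.
    Includes the experiment protocols of the underlying phenomenology:
    single-spike threshold search, duty-cycle by amplitude phase diagrams,
    thalamic duty-cycle response curves, chimeric channel addition, and
    thalamic-input sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
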