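Package: locomotoR
Title: Brainstem-Spinal Circuit Simulation of Locomotor Frequency and Gait
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Rate-model simulation of a bilateral brainstem-spinal locomotor
    circuit in which mesencephalic locomotor region nuclei (cuneiform and
    pedunculopontine) drive four spinal rhythm generators through
    reticulospinal relays, commissural interneurons and long propriospinal
    neurons. Provides the default connectome, deterministic and stochastic
    integration of the population dynamics (persistent-sodium half-center
    oscillators plus leaky rate units), continuation sweeps of stimulation
    strength with hysteresis detection, quadruped gait classification from
    inter-limb phase differences, noisy gait-probability maps, inhibitory
    drive grids, lesion experiments and connection-weight robustness
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, Rcpp, yaml, jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), deSolve, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'RcppExports.R'
    'gait.R'
    'dynamics.R'
    'connectome.R'
    'engine.R'
    'config.R'
    'network-methods.R'
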