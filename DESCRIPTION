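Package: tcwaves
Title: Closed-Loop Thalamocortical Lattice Model of Traveling Brain Waves
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a two-dimensional closed-loop thalamocortical network
    of excitable two-state neurons (a cortical sheet coupled to thalamic
    relay and reticular layers, plus a reduced two-layer variant) and
    quantifies the traveling waves it produces. Provides phase-plane and
    activation-threshold analysis for the single-neuron models, builders for
    lattice, clustered and cross-layer connectivity, post-inhibitory-rebound
    delay chains for transmission delays, a stochastic Euler integrator with
    absorbing boundaries and named scenario presets, and a wave-analysis
    toolkit (wavefront segmentation, nearest-edge speed, kymographs,
    dominant frequency, lurch index, wave area, duration and direction)
    together with geometric fixture movies with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
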