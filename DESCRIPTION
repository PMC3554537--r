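Package: traumanet
Title: Post-Traumatic Homeostatic Plasticity in Lattice Cortical Network Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates a two-dimensional lattice network of Morris-Lecar
    neurons subject to deafferentation trauma and homeostatic synaptic
    plasticity (HSP). The upregulating (glial, TNF-alpha-like) arm of HSP
    can be spatially restricted to the presynaptic partner set of each
    neuron and further partitioned into astrocytic microdomains, including
    a two-domain scheme that segregates inputs by presynaptic
    deafferentation status. Provides network construction with
    footprint-limited connectivity, short-term synaptic depression,
    stochastic afferent drive, firing-rate calibration, and an analysis
    layer for paroxysmal-burst detection, spatial rate profiles,
    cross-covariance, and boundary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
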