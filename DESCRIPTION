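Package: hemeET
Title: Electron Tunneling Pathways and Marcus Analysis for Heme Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-simulation analysis of transmembrane heme-to-heme electron
    transfer. Implements the semi-empirical tunneling pathway model (covalent,
    hydrogen-bond and through-space decay factors with a Dijkstra best-path
    search on trajectory snapshots), linear-response / Marcus estimation of
    reaction free energies and reorganization energies from vertical
    energy-gap time series (with block averaging, component decomposition and
    an ergodicity factor), coupling-coherence ensemble statistics, and
    two-site occupancy analysis of a dioxygen-binding cavity. A synthetic-data
    module generates Gaussian and bimodal gap series, telegraph distance
    trajectories and toy molecular structures with known optimal pathways so
    that every stage is testable without the original trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
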