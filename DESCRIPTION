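Package: chorioflux
Title: Electric-Circuit Simulation of Choriocapillaris Lobular Perfusion
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Steady-state simulation of blood flow in the choriocapillaris,
    the lobular capillary bed of the choroid, as a direct-current resistor
    network solved by Kirchhoff nodal analysis. Lobules are modelled as
    dual-layered triangulated hexagons with a central anode (feeding
    terminal arteriole), collector-venule boundary edges scaled by
    Poiseuille's fourth-power law, and draining-venule cathodes at
    alternating corners, tiled into a honeycomb lattice. Provides embolism
    experiments (single terminal-arteriole disconnection and sectorial
    posterior-ciliary-artery occlusion), per-lobule influx and average-current
    metrics with percentage ratios against a fully perfused reference,
    boundary-resistance sweeps, randomized scattered and segmental embolism
    scenario generators, current-field rendering, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    jsonlite,
    yaml,
    igraph,
    optparse,
    tools,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'circuit-network.R'
    'solver.R'
    'lobule-mesh.R'
    'scenario.R'
    'metrics.R'
    'synthetic.R'
    'io.R'
    'render.R'
    'cli.R'
    'chorioflux-package.R'
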