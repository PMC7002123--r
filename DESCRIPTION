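Package: visionflock
Title: Collective Behavior Driven Purely by the Visual Projection Field
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Agent-based simulation of collective motion in which individuals
    respond only to a binary visual projection field: disk- or sphere-shaped
    agents accelerate and turn according to the angular area subtended by
    neighbors on an omnidirectional retina and to the edges of that
    projection.  The interplay of subtended-angle repulsion and edge
    attraction yields short-range repulsion, long-range attraction, a
    characteristic equilibrium distance, and a range of collective states
    (polarized lines, milling, fluid swarms, crystal-like packings) without
    any explicit representation of neighbor positions or velocities.
    Provides exact occlusion-resolved arc geometry on the 2D retina, a
    discretized spherical retina for the cylindrical-kinematics 3D variant,
    order-parameter metrics (polarization, nearest-neighbor distances,
    swarm extents, collision detection), deterministic seeded experiment
    drivers for parameter sweeps, and plain-text trajectory input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
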