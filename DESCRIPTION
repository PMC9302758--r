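Package: maskfit
Title: Face-Mask Contact Pressure Simulation by Reduced Shell Finite Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Efficient simulation of the contact pressure between a human face and a
    rigid facial mask for ergonomic mask design. A triangulated face surface (from a
    3D scan or the built-in synthetic generator) is modelled as a single-layer
    triangular flat-shell finite element mesh with soft-tissue material constants;
    the mask contact line is parameterized as a periodic cubic spline through a few
    designer-chosen reference points and sampled into rigid contact nodes. Static
    condensation (Guyan reduction) restricts the face stiffness to the master nodes
    that any candidate mask can touch, and a Lagrange-multiplier node-to-node contact
    solve with an active-set loop yields contact forces, which tributary areas convert
    to nodal pressures. Design sweeps enumerate reference-point adjustments and rank
    candidates by mean and spread of contact pressure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
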