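Package: cathfem
Title: Quasi-Static Catheter and Guidewire Simulation by Total Potential
    Energy Minimization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Interactive-rate simulation of catheters and guidewires
    navigating triangulated blood-vessel geometry. The catheter
    centerline is discretized in tangent space; Kirchhoff bending
    energy, Hooke-law wall-penalty energy against vessel triangles, and
    the work of external forces are assembled as quadratic forms over
    the nodal tangents, and each push or pull input is answered by
    solving a small symmetric positive-definite linear system inside an
    active-set contact loop. Includes tube-phantom generators, OBJ/STL
    mesh input/output, node-versus-triangle collision detection,
    arc-length curve resampling and RMS deformation metrics, and a
    scripted simulation driver with convergence sweeps over segment
    length and input stepsize.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
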