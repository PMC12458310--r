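Package: cellspring
Title: Coarse-Grained Bead-Spring Simulation of Cortical Tension and
    Neurite-Like Protrusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-dimensional coarse-grained bead-spring model of a single
    cell: a plasma-membrane ring and a nuclear-envelope ring connected by
    radial actin filaments whose terminal "head" beads adhere to the membrane
    through a short-range attraction of tunable well depth (modelling cortical
    membrane-actin tension), while the membrane ring carries a tunable
    stretching constant (modelling membrane tension). Overdamped Langevin
    dynamics with a deterministic filament-growth protrusion engine, a
    constant-energy velocity-Verlet mode for force validation, protrusion
    morphometrics (projection length, persistence, circularity), and a
    parameter-sweep pipeline over adhesion strength and membrane stiffness
    with replicate seeds and mean +/- SEM summaries. Trajectories are written
    as extended-XYZ; metrics and sweep tables as CSV; cell contours as SVG.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
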