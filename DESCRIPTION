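Package: aclimpinge
Title: Virtual Simulation of ACL Graft Impingement in the Intercondylar Notch
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for three-dimensional virtual simulation of graft
    impingement after anatomical single-bundle anterior cruciate ligament
    (ACL) reconstruction. Provides a watertight triangle-mesh toolkit with
    STL input/output, rigid transforms and a voxel-based Boolean
    intersection-volume kernel; quadrant reference frames that convert
    percentage footprint coordinates into 3D tunnel positions on the femur
    and tibia; virtual cylindrical grafts; a parametric synthetic-knee
    generator with analytic ground truth for validation; a factorial
    experiment runner over footprint positions, graft diameters and knee
    flexion angles; and the accompanying statistical battery (t-tests,
    one-way and two-way ANOVA with partial eta squared).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
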