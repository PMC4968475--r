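Package: wallstokes
Title: Hydrodynamic Force and Torque on Microspheres near Microchannel Walls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes the hydrodynamic force and torque on a micron-scale
    sphere translating, rotating or held stationary near the wall of a
    parallel-plate microchannel, under either a linear (constant shear) or a
    fully developed parabolic velocity profile. The steady Stokes equations
    are solved with a single-layer boundary-element method built on the
    image-system Green's function for a no-slip plane wall, so the thin
    lubrication gap between sphere and wall is resolved without volume
    meshing. Includes the force-free/torque-free mobility problem for freely
    rolling spheres, wall-correction reference factors for the classical
    constant-shear model, batch sweeps over wall shear stress, and a
    synthetic-video pipeline that renders half-coated fluorescent (Janus)
    microspheres and recovers their translational and rotational velocities
    by centroid tracking and projected-area periodicity, as used in cell
    rolling adhesion assays.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    png,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
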