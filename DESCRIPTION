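Package: fvstent
Title: Fast Virtual Stenting of Braided Flow-Diverter Devices in Vessel Phantoms
Version: 0.1.0
Authors@R: person("fvstent", "developers", role = c("aut", "cre"),
    email = "fvstent@example.org")
Description: Tools for simulating the deployment of braided, self-expanding
    intracranial stents (such as the LVIS flow-diverter family) inside a
    vessel lumen surface mesh. The pipeline extracts a parent-artery
    centerline by maximal-inscribed-sphere marching, expands a cylindrical
    simplex-style deformable tube until it apposes the vessel wall, maps a
    multi-wire helical braid pattern onto the deployed surface, and sweeps
    the wires into watertight 3D solids ready for CFD meshing. Parametric
    vessel and sidewall-aneurysm phantoms with analytic ground truth make
    every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
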