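Package: vessim
Title: Vascular Intervention Simulation Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational core of a percutaneous coronary intervention (PCI)
    training simulator. Extracts curve skeletons (centerlines) from vessel
    surface meshes by Laplacian mesh contraction with cotangent weights,
    adaptive subdivision, local PCA joint/branch classification, joint
    clustering, skeleton growing and cubic B-spline fitting. Models guidewires
    and catheters as chains of rigid rods with intrinsic bias angles,
    equilibrated by potential-energy minimization with a single-detection,
    force-corrected collision response against the vessel wall, adaptive rod
    splitting/merging, push/pull/twist maneuvers and wall-rupture events.
    Renders fluoroscopy-like images by ray-cast material thickness and
    Beer-Lambert X-ray attenuation. Ships parametric vascular phantoms
    (cylinders, bent tubes, bifurcations) with analytic ground-truth
    centerlines so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    splines,
    igraph,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
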