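Package: flow4d
Title: Postprocessing of 4D Flow MRI Velocity Fields: Segmentation, Wall
    Shear Stress, Energy Loss and Field Comparison
Version: 0.1.0
Authors@R:
    person("flow4d", "developers", email = "flow4d@example.org",
           role = c("aut", "cre"))
Description: Tools for postprocessing time-resolved three-directional
    phase-contrast (4D flow) MRI velocity volumes of large vessels and for
    comparing them against simulated flow fields. Provides lumen
    segmentation from phase velocity images (thresholding, 3D region
    growing, velocity-guided boundary refinement), watertight surface
    extraction with Laplacian smoothing, wall shear stress estimation from
    near-wall velocity sampling, viscous flow energy loss under laminar,
    Smagorinsky LES and RNG k-epsilon eddy-viscosity closures,
    through-plane flow-rate integration, region-wise Pearson
    correlation/error statistics between two velocity fields, and analytic
    flow phantoms (Poiseuille, Womersley, rigid rotation, branching tube)
    with a phase-contrast degradation model (partial volume, noise,
    velocity-encoding aliasing) for validation. Volumes are read and
    written as NIfTI-1, NRRD and legacy VTK structured points; surfaces as
    STL, PLY and VTP.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
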