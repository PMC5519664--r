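# flow4d

Postprocessing of 4D flow MRI velocity fields: vascular lumen
segmentation, wall shear stress, viscous energy loss, flow rates, and
voxelwise comparison against simulated flow — validated end to end on
analytic flow phantoms.

## Who this is for

4D flow (time-resolved, three-directionally velocity-encoded
phase-contrast) MRI delivers a velocity vector **u**(x) in every voxel of
a vascular territory such as the aortic arch. Turning those voxels into
hemodynamic quantities — where is the wall, how hard does blood shear
against it, how much kinetic energy is dissipated, does measured flow
obey conservation — requires a chain of image-processing and numerical
steps that is usually hidden inside in-house code. `flow4d` implements
that chain as a tested, scriptable R package, together with analytic
phantoms (Poiseuille, Womersley, rigid rotation, branching tube) whose
wall shear, dissipation and flow are known in closed form, so every stage
can be checked against ground truth rather than against another program.

It is aimed at researchers validating CFD against phase-contrast MRI,
and at anyone who needs reference implementations of the standard
postprocessing operators on structured velocity grids.

## What it computes

* **Segmentation** — threshold on the speed image |u|, 3D region
  growing from a seed, velocity-guided boundary refinement, scripted
  voxel edits; surface extraction at iso-level 0.5 (watertight dual
  contouring) followed by Laplacian smoothing.
* **Wall shear stress** — no-slip wall, trilinear velocity sample at a
  half-voxel depth along the inward normal, tangential projection:

  WSS = μ ‖u_t(x_f − d·n̂)‖ / d   [Pa],  d = half the voxel pitch.

* **Energy loss** — the viscous dissipation integral over the lumen V

  EL = ∫_V (μ + μ_t) Σ_ij ½ (∂u_i/∂x_j + ∂u_j/∂x_i)² dV   [W]

  with eddy viscosity μ_t = 0 (laminar), μ_t = (C_s Δ)² √(2 S_ij S_ij)
  (Smagorinsky LES, C_s = 0.1), or μ_t = C_μ ρ k²/ε (RNG k–ε,
  C_μ = 0.0845, k and ε supplied from a solver). The integral is split
  into the outermost voxel shell ("boundary layer") and the core.
* **Flow rate** — Q = ∮ (u·n̂) dA over a rasterized cut plane, plus cubic
  spline waveform interpolation of per-phase flows.
* **Comparison** — after trilinear resampling onto a common grid,
  per-region (AAo / arch / DAo) and per-component (u/AP, v/RL, w/SI)
  Pearson r with p-value and mean ± SD absolute error in m/s.
* **Phantoms and PC-MRI degradation** — analytic fields voxelized at
  clinical resolutions (defaults 0.885×0.885×1.0 mm), degraded by box
  partial-volume averaging, Gaussian noise and venc phase-wrapping, which
  reproduces the characteristic underestimation of flow in small vessels.

Internal units are SI (m, s, Pa, W); grid metadata is in mm as is
conventional for medical volumes. I/O: NIfTI-1, NRRD and legacy VTK
structured points for volumes; STL, PLY and VTP for surfaces; JSON/CSV
for reports.

## Worked example

```r
library(flow4d)

# steady pipe flow, R = 10 mm, Q = 5 L/min, voxelized at 1 mm
ph <- gen_phantom(phantom_spec("poiseuille", radius = 10, length = 40,
                               spacing = c(1, 1, 1)))
mesh <- extract_surface(ph$mask)
mesh
#> tri_mesh: 4080 vertices, 8156 faces, area 3281.666 mm^2

w <- compute_wss(mesh, ph$field)
w
#> wall_shear_field: 8156 of 8156 faces valid, area-averaged |WSS| 0.3096718 Pa
ph$truth$wss           # analytic 4*mu*Q/(pi*R^3)
#> [1] 0.4244132

el <- compute_el(ph$field, 1, ph$mask)
el
#> energy_loss_result (laminar): total 0.0002882 W = boundary layer 9.724e-05 W + core 0.000191 W (2654 + 10179 voxels)
ph$truth$el            # analytic 8*mu*L*Q^2/(pi*R^4)
#> [1] 0.0002829421

q <- flow_rate(ph$field, 1, ph$mask,
               plane = list(origin = c(0, 0, 20), normal = c(0, 0, 1)))
q$volume_flow          # m^3/s; analytic value is 8.333e-05
#> [1] 8.322938e-05
q$mass_flow            # kg/s at rho = 1060
#> [1] 0.08822314
```

Reading the numbers: the volume flow is within 0.2% of truth and the
energy loss within 2%. The whole-mesh average WSS (0.31 Pa) sits below
the analytic wall value because the phantom's flat end caps carry zero
tangential stress; restricted to lateral wall faces the estimate is
0.37 Pa, 13% below truth at this 1 mm resolution and converging to −2%
at 0.5 mm — the resolution-driven WSS underestimation expected of
voxel-grid data.

## Command line

A full pipeline (phantom → degrade → segment → WSS/EL/flow → compare) is
driven by one JSON config; see
`inst/extdata/example_config.json`:

```sh
Rscript -e 'flow4d::flow4d_main()' run \
    --config inst/extdata/example_config.json --out out_dir --seed 1
```

Every run writes a `manifest.json` recording package version, config and
seed, so results are reproducible byte-for-byte.

## Vignette

`vignettes/flow4d-methods.Rmd` documents the model assumptions, the
numerical choices (stencils, iso-surface extraction, sampling depth,
plane integration), the phantom and degradation parameters and what the
synthetic validation does and does not establish.
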