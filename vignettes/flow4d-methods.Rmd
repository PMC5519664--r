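---
title: "flow4d: models, numerics and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{flow4d: models, numerics and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flow4d)
```

## Scope and model

`flow4d` postprocesses a 3-component velocity field sampled on a regular
voxel grid — the output of a 4D flow (phase-contrast) MRI acquisition or
of a flow simulation resampled onto such a grid — into the quantities
used in clinical hemodynamics: a segmented lumen, a smoothed wall
surface, wall shear stress (WSS), viscous flow energy loss (EL),
through-plane flow rates, and region-wise agreement statistics between
two fields. Blood is treated as an incompressible Newtonian fluid with
dynamic viscosity μ = 0.004 Pa·s and density ρ = 1060 kg/m³ by default;
both are parameters of `fluid_properties()` because the literature
varies and because mass flows scale linearly with ρ.

All physics is computed in SI units; voxel spacing and mesh coordinates
are carried in millimetres (the convention of medical volume formats)
and converted at the point of use. Voxel indices are 1-based, a voxel's
value lives at its centre, and the world position of voxel (i,j,k) is
`origin + (i-1, j-1, k-1) * spacing`. Velocity components are stored in
the fixed anatomical order (AP, RL, SI); the geometry's axis labels map
grid axes to anatomical directions. Time-resolved fields are stored with
all frames, but every downstream operator acts on one selected frame —
in clinical practice the peak-systolic phase, which is the only phase in
which velocity-based segmentation is reliable (diastolic phase-contrast
images carry too little signal to define the wall, which is also why
diastolic segmentation is a non-goal here).

## Segmentation

The lumen is segmented from the *speed* image |u| (the "phase velocity"
information), not from anatomical magnitude images: at peak systole the
moving-blood compartment is exactly the bright region of the speed map.
The chain is

1. `threshold_segment()` — voxels with |u| ≥ t. The coarse threshold is
   a free parameter (there is no universally correct value; it depends
   on venc and noise floor), exposed with no default.
2. `region_grow()` — connected component of the seed, 26-connectivity by
   default. 26 is the permissive choice: at clinical resolution a vessel
   a few voxels wide can be face-disconnected across a bend while still
   being one lumen. 6-connectivity is available for stricter behaviour.
3. `refine_boundary()` — the automated stand-in for voxel-by-voxel
   manual boundary editing against the velocity images: boundary voxels
   (those with a background face-neighbour) slower than a second
   threshold are culled, iterated to a fixed point. It is erosive by
   construction and cannot disconnect-and-regrow.
4. `edit_mask()` — residual manual corrections as an explicit,
   replayable edit list, so a "manual" segmentation is a reproducible
   artifact rather than an interactive session.

Boundary detection uses 6-connectivity throughout (here and in
`boundary_layer_mask()`) so that "boundary voxel" coincides with
face-adjacency erosion.

## Surface extraction

`extract_surface()` builds the wall at iso-level 0.5 of the binary
lumen indicator. Internally it uses *naive surface nets* (dual
contouring): one vertex per surface-crossing grid cell, placed at the
centroid of the cell's edge crossings, and one quad per sign-change grid
edge. We chose this over a table-driven marching-cubes pass deliberately:

* on a *binary* field, classic marching cubes produces a heavily
  staircased triangulation whose area overestimates a 10 mm sphere's by
  ~9% at 1 mm voxels — too biased to be useful for WSS area-averaging —
  while the dual surface is within ~3% and converges with resolution;
* the dual mesh is watertight by construction (every quad edge is shared
  by exactly two quads), with no ambiguous-case holes and no case
  tables to maintain.

Normals are oriented outward (lumen → exterior), verified globally by
the signed enclosed volume. The volume is padded by one background layer
so surfaces touching the grid edge still close.

`smooth_laplacian()` then applies the classic uniform-weight vertex
relaxation `v ← v + λ(mean(neighbours) − v)`. Defaults are 10 iterations
at λ = 0.5: enough to remove residual voxel texture, while shrinking the
enclosed volume of the 10 mm sphere fixture by ~6% (the tests enforce
< 15%; unchecked Laplacian smoothing collapses closed surfaces, which is
why the iteration count is a visible parameter and not hidden).

## Wall shear stress

With a no-slip wall, the shear stress is μ ∂u_t/∂n at the wall. On voxel
data the gradient is approximated by a one-sided finite difference
between the wall (u = 0) and a point a distance d inside the lumen along
the inward normal:

WSS = μ · ‖u_t(x_f − d n̂)‖ / d,

where x_f is the face centroid, u_t = u − (u·n̂)n̂ the tangential
projection, and the sample is trilinear. The default d is half the mean
voxel spacing — sampling a *half voxel inside* is the established
compromise: deeper samples bias the gradient low (the velocity profile
is curved), shallower samples are dominated by partial-volume zeros just
outside the wall. The WSS vector is tangential by construction and faces
whose sample point leaves the grid are flagged invalid rather than
silently zeroed.

On the voxelized Poiseuille pipe (R = 10 mm, Q = 5 L/min) the
area-averaged lateral-wall WSS is 13% below the analytic
4μQ/(πR³) = 0.424 Pa at 1 mm voxels and 2% below at 0.5 mm: WSS from
gridded velocity data is intrinsically resolution-limited and biased
low, the same behaviour reported for in-vivo 4D flow WSS throughout the
literature. The acceptance suite pins both the 20% envelope and the
convergence direction.

## Strain rate and energy loss

`strain_rate()` computes ∂u_i/∂x_j restricted to the mask: central
differences where both face-neighbours along an axis are in-mask,
second-order one-sided differences (`(−3u₀+4u₁−u₂)/2h`) at the lumen
edge where two same-side neighbours exist, first-order one-sided where
only one does, and exclusion of the voxel from the valid set where a
direction has no in-mask neighbour at all. Gradients never reach across
the wall — the exterior zeros are an imaging convention, not fluid. The
valid-voxel count is reported so excluded wall voxels are visible.

Energy loss integrates the dissipation function over valid voxels:

EL = Σ (μ + μ_t) · Σ_ij ½(∂u_i/∂x_j + ∂u_j/∂x_i)² · ΔV  [W],

equal to 2(μ+μ_t) S:S per unit volume. Three closures are provided:
laminar (μ_t = 0); Smagorinsky LES, μ_t = (C_s Δ)²√(2 S_ij S_ij) with
C_s = 0.1 and Δ defaulting to the cube root of the voxel volume (the
natural "local grid size" of a structured grid); and RNG k–ε,
μ_t = C_μ ρ k²/ε with C_μ = 0.0845, where k and ε must come from a
turbulence-transport solution — solving those transport equations is a
CFD-solver task and out of scope, so the package evaluates the formula
pointwise from supplied volumes, with μ_t forced to 0 where
ε < 10⁻¹² m²/s³ to avoid division blow-up. Since μ_t ≥ 0 in every
closure, EL is monotone: laminar ≤ LES and laminar ≤ RNG, matching the
physical expectation that eddy viscosity only adds dissipation.

EL is reported split into the outermost voxel shell (the "boundary
layer" in the MRI sense) and the core, because most dissipation
concentrates in the near-wall velocity gradient and that is exactly
where MRI resolution is weakest; the two compartments sum to the total
exactly by construction.

On the Poiseuille pipe at 0.5 mm the laminar EL is within 0.1% of the
analytic 8μLQ²/(πR⁴) — central differences are exact on the parabolic
profile, so the residual error is purely domain voxelization — and a 6³
brute-force triple-loop implementation of the same integral agrees with
the vectorized path to 1e−12 relative, which guards the index algebra.

## Flow rate and waveforms

`flow_rate()` rasterizes a cut plane at the smallest voxel pitch,
samples velocity trilinearly, keeps raster points where the trilinearly
interpolated lumen indicator is ≥ 0.5, and sums (u·n̂)ΔA. Midpoint
integration of the smooth profile makes this accurate to well under 1%
even for vessels a few voxels wide; the sign follows the supplied
normal, so reversing the plane negates the flow exactly.
`interpolate_waveform()` wraps a cubic interpolating spline through
per-phase flows (≥ 4 samples, strictly increasing times) and refuses to
extrapolate.

## Field comparison

`resample_to_grid()` brings the second field (typically a simulation)
onto the reference grid by trilinear interpolation — exact for linear
fields, the standard choice for this task. Scattered point-cloud input
is accepted through inverse-distance weighting of the nearest samples;
this is a documented fallback (no scattered linear interpolant exists in
the supported dependency stack), adequate for dense CFD clouds but not
for sparse data. `partition_regions()` splits the lumen into three
regions by two user-supplied cut planes — ascending aorta, arch,
descending aorta in the intended application; no automatic anatomical
plane placement is attempted because no robust convention exists.
`compare_fields()` then reports, per region and per velocity component,
the Pearson correlation with its two-sided p-value (raw, no
multiple-testing correction) and the mean ± SD of the absolute voxelwise
component difference in m/s. "Error" is defined as *absolute* difference
averaged per voxel: published tables of the form "0.068 ± 0.054 m/s"
with SD < mean are consistent with an unsigned voxelwise error, and a
voxel-weighted mean is the natural reading of "area-averaged" on an
isotropic-in-plane grid; both conventions are stated rather than claimed
to match any particular prior implementation. Cells with fewer than two
joint non-missing voxels are reported NA, never raised as errors, and
sample counts make dropped voxels visible.

## Phantoms: the stated world

The synthetic module generates the validation world; its defaults are
fixed once and are not tuning knobs.

* **Resolutions** default to 0.885 × 0.885 × 1.0 mm, with
  1.25 × 1.25 × 2.0 mm as the degraded/"adult-scan" target — the two
  voxel sizes of representative clinical 4D flow protocols (child and
  adult scanner respectively). Womersley phantoms default to 16 frames
  per cycle, inside the clinical 12–20 views-per-phase range.
* **Poiseuille**: parabolic profile for Q = 5 L/min (a physiologic
  aortic systolic flow), R = 10 mm. Ground truth: u_max = 2Q/(πR²),
  wall shear 4μQ/(πR³), dissipation 8μLQ²/(πR⁴) (≡ ΔP·Q, checked as an
  identity in the tests).
* **Womersley**: the classic oscillatory pipe solution
  u(r,t) ∝ Re{[1 − J₀(i^{3/2}α r/R)/J₀(i^{3/2}α)] e^{iωt}}, normalized
  so the flow waveform is exactly Q_amp·cos(ωt); α defaults to 13
  (adult-aorta scale) and ω follows from α = R√(ω/ν). Complex Bessel
  functions use the ascending series, accurate for |z| ≲ 25, which
  covers physiologic Womersley numbers.
* **Rigid rotation**: solid-body swirl — strain-free, EL = 0, zero net
  through-flow; the canonical null case for the dissipation operator.
* **Branching**: a parent tube (R = 10 mm) splitting into two Poiseuille
  children (6 and 3 mm — the small one deliberately neck-vessel-sized)
  with flows summing exactly to the parent's, split ∝ r³ (Murray's law)
  by default. The junction velocity field is piecewise-analytic, not a
  solved flow; it exists to make conservation checks and partial-volume
  experiments possible, not to model bifurcation fluid dynamics.

`degrade_pcmri()` emulates why PC-MRI underestimates flow in small
vessels with the minimal mechanism: box partial-volume averaging onto
the coarser scan grid (the average includes the true zero velocities
outside the wall, so edge voxels are biased low), additive Gaussian
component noise, and phase-wrapping of components beyond venc by
multiples of 2·venc. All randomness flows through one seed and the
operation is bit-reproducible. The model makes no claim about k-space,
eddy currents or acceleration artifacts; consequently a green
underestimation test establishes that the *analysis chain* responds to
resolution loss the way real data does, not that the generator is a
scanner simulation.

## What the synthetic validation does not establish

The phantoms are straight, rigid, steady (or single-harmonic) tubes.
They cannot exercise secondary/helical flow from arch curvature,
turbulence, wall motion, or segmentation on noisy anatomical contrast —
so the acceptance suite validates operator correctness and convergence,
not clinical accuracy in vivo. Curved-tube (Dean flow) phantoms were
considered and excluded: there is no clean closed form at physiologic
Dean numbers, and an approximate oracle would test nothing.

## Numerical choices and degenerate inputs

* Trilinear interpolation returns NA outside the hull of voxel centres
  (with a 1e−9 edge tolerance); NA corner values propagate — missing
  data never fabricates numbers.
* The marching iso-level (0.5), the boundary connectivity (6), the
  region-growing default (26), the WSS depth (half voxel), Δ (cube root
  of voxel volume) and the ε floor (1e−12) are documented defaults, each
  overridable.
* Empty masks, seeds on background (warning + empty mask), planes that
  miss the lumen, out-of-range frames, non-increasing waveform times,
  < 4 spline samples, λ outside (0,1], unsupported formats: all are
  explicit, classed errors (`flow4d_*_error`) rather than silent
  misbehaviour.
* The pipeline validates its config up front and reports *all* missing
  keys at once; stage failures name the stage; every run writes a
  manifest with version, config and seed.

## Known limitations

* WSS at 1 mm voxels is biased ~10–15% low on a 20 mm vessel; users
  should treat absolute WSS from clinical-resolution data as
  systematically underestimated (the package reproduces, rather than
  hides, this property of the modality).
* Surface-net meshes are watertight but can be non-manifold at
  voxel-corner pinch configurations; none arise in tube/ball topologies.
* The RNG k–ε closure consumes k/ε; it cannot be used on MRI-only data.
* Oscillatory shear index and time-averaged WSS are out of scope
  (single-phase analysis).
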