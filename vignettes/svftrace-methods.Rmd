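---
title: "Methods: convergence-index seeding, open-curve snake tracing and sliding-band radius estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: convergence-index seeding, open-curve snake tracing and sliding-band radius estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svftrace)
```

# The problem

Reconstructing a neuron's anatomy from a 3-D fluorescence microscopy stack
means recovering, without manual editing, (i) the centerline tree of its
axonal and dendritic arbors, (ii) the local thickness along every branch, and
(iii) a surface model usable for visualization and simulation. `svftrace`
implements a complete pipeline for this task: convergence-index seeding, an
open-curve snake tracer with a gradient-vector-flow external force and
seed-label collision handling, per-node cross-section contour estimation with
a 2-D sliding band filter, SWC export, and evaluation metrics against
ground-truth centerlines. A synthetic-phantom module generates ground-truthed
tubular volumes so every stage is testable without external data.

All coordinates are 0-based voxel coordinates with voxel centers at integers;
`x` varies fastest within a slice and `z` indexes slices. All filter
parameters are in voxel units; anisotropic physical spacing is carried on the
volume and applied only at SWC export.

# Seed detection: the sliding volume filter

The voxel convergence index (VCI) at a sample `P` relative to a center `O`
is the cosine of the angle between the image gradient at `P` and the
direction from `P` to `O`. Inside a bright tube, gradients on the wall point
toward the centerline, so VCIs measured toward a centerline voxel are close
to +1 on the wall shell.

The sliding volume filter (SVF) at a voxel `O` averages, over `M = 2L^2`
directions on a polar grid (azimuth divided into `2L` parts, polar angle
into `L`; the grid double-covers directions near the poles and no area
weighting is applied — the estimator is reproduced as classically defined,
not improved), the best radial *band* of VCIs: for each direction the band
of thickness `d` (the `d + 1` integer radial offsets in `[r - d/2, r + d/2]`)
slides its center `r` over the strict integer range `(R_min, R_max)` and
takes the maximal mean VCI, with ties broken toward smaller radii. Off-grid
samples use trilinear gradient interpolation; samples outside the volume and
samples with gradient magnitude below `1e-6` contribute 0. The response lies
in `[-1, 1]`, is invariant to global intensity scaling (only gradient
*directions* enter), and peaks on centerlines of tube-like convex regions.

Voxels with response above the threshold `T = 0.7` become raw seeds. The
default filter geometry (`rad = 20`, `d = 8`, `L = 20`, `R_min = 5`,
`R_max = rad - d/2 = 16`) suits neurites up to roughly 8 voxels in radius;
brighter-field data or large somata need a larger support radius.

## Gradient scale

Gradients are Gaussian-smoothed central differences. The smoothing scale
`sigma_g` must match the structure: too small and, under noise, the band
samples away from the wall carry direction-random noise gradients that cap
the SVF response well below `T` (at `sigma_g = 1` the response on the
reference helix under noise variance 0.04 tops out near 0.5, so `T = 0.7`
finds nothing); too large and neighbouring structures bleed together. The
package default is `sigma_g = 2` voxels — half the radius of the thinnest
structure of interest in the reference world — and one default is used for
every experiment, noiseless or noisy.

## Ridge refinement

A point is on a centerline ridge when the gradient is orthogonal to the two
cross-sectional Hessian eigenvectors (`ev2`, `ev3`, the largest-magnitude
pair; eigenvalues are ordered `|l1| <= |l2| <= |l3|` and `ev1` is the
centerline direction). The classical criterion thresholds the raw dot
products `|ev_i . grad I| < 0.001`; on an integer voxel grid of 8-bit data
this keeps essentially nothing — the in-plane gradient at the voxel *nearest*
the centerline is already of order 10 intensity units per voxel, because no
voxel center sits exactly on the ridge. The printed tolerance presumes
continuum evaluation.

The package's default criterion is the equivalent discrete, scale-invariant
form: the first-order (Newton) estimate of the in-plane offset to the ridge,

```
offset = sqrt( (ev2.g / l2)^2 + (ev3.g / l3)^2 )  <  1 voxel,
```

i.e. "the Newton step onto the ridge is shorter than one voxel". One voxel is
the estimate's real accuracy scale: the nearest voxel center can sit
`sqrt(2)/2 ≈ 0.71` from the axis in-plane, and the nonlinearity of realistic
intensity profiles inflates the first-order estimate beyond that, so
sub-voxel cutoffs systematically starve axis-aligned tubes of seeds. Flat
points (tiny gradient *and* curvature) pass; strong off-ridge gradients are
rejected. The literal dot-product form remains available
(`ridge_filter(mode = "dot", tol = ...)`) for tolerances calibrated to a
data set's gradient scale. The Hessian scale is `sigma_h = 1.5` voxels.

Final seeds are sorted by descending response (ties broken by lexicographic
position, so the list is independent of input order) and greedily suppressed
at `min_spacing = 2` voxels.

# SVF enhancement and gradient vector flow

Seed responses also enhance the volume for tracing:
`I_svf = 15 * sqrt(min(I * (1 + SVF), 255))` (negative inner products clamp
to 0). This brightens convergence centers and compresses dynamic range. The
external snake force is the diffusion-regularized gradient vector flow (GVF)
of the enhanced volume scaled to `[0, 1]`: starting from `u = grad f`,
iterate `u <- u + dt (mu lap(u) - (u - grad f) |grad f|^2)` with `mu = 0.1`,
50 iterations and `dt = min(1, 1/(6 mu))` (the explicit-diffusion stability
bound). The field is then normalized to unit vectors — but only where its raw
magnitude exceeds 1% of the field maximum, else zeroed. Without that floor,
the numerical residue exactly on a centerline (where opposing flows cancel)
is blown up to arbitrary unit vectors and biases the snake equilibrium by
almost half a voxel; with it, an on-axis curve is a fixed point of the
deformation to machine precision.

# Open-curve snake tracing

A snake is an open polyline `c(s)`, `s in [0, 1]`, that minimizes a sum of
internal energy (elasticity `alpha |c_s|^2` plus stiffness
`beta |c_ss|^2`, with `beta = 0` at the two end nodes) and external energy
(the image term whose negative gradient is the GVF field, plus an endpoint
stretch term). Each deformation step solves the standard semi-implicit
update `x_t = (gamma I + A)^{-1} (gamma x_{t-1} + F(x_{t-1}))` per
coordinate, with `A` the pentadiagonal internal operator. `A`'s two end rows
are zero (the ends are driven by the stretch force), which makes straight,
evenly spaced curves exact fixed points — there is no artificial shrinkage —
while all eigenvalues remain real and non-negative. Defaults follow the
classical parameterization: `alpha = 0.8`, `beta = 0.2`, `gamma = 2`,
`t_max = 10` iterations per extension cycle.

The printed update is sometimes written with the enhanced image inside the
inverted operator; this package reads that as the identity matrix times
`gamma` (the standard semi-implicit step), which is the only reading that
keeps the operator well conditioned for arbitrary images.

The stretch force acts only at the two ends, along the outward unit tangent,
with the tubeness magnitude `| sqrt(|l2 l3|) / (|l1| + 0.01) - 1 |`: much
larger than 1 on a tube (the end grows), near 0 where the eigenvalues become
comparable (a blob-like terminal), and exactly 1 on perfectly flat
background. Because the raw magnitude is unbounded on a clean centerline,
the *applied* force is capped at `stretch_cap = 1` (the same unit scale as
the normalized flow); the raw magnitude is still what the convergence test
sees.

Curves are initialized with 3 nodes from the strongest unlabeled seed along
`±ev1`, extended one `extend_step = 1.5`-voxel node per growing end per
cycle, re-deformed, and resampled to `node_spacing = 1.5` voxels (consecutive
node gaps stay within `[0.5, 2]` times the spacing). An end stops growing
when any of these hold:

* the raw stretch magnitude stays below `stretch_eps = 0.2` for 3
  consecutive extensions (the printed convergence rule);
* the end sits in background intensity (< 1 of 255) for 3 consecutive
  extensions;
* it would leave the volume;
* it stalls — net end displacement below 1 voxel over 3 consecutive
  extensions. The discrete Hessian rarely *samples* the narrow isotropic
  window at a tube cap (the spectrum jumps from tube-like to cap-like
  between extensions), so the printed rule alone can leave an end hovering
  in equilibrium between the inward flow pull and the outward stretch push;
  stagnation is the operational form of "the forces balance".

## Seed labeling and collision handling

During extension every unlabeled seed within the claim radius
(`max(2, mean radius)` voxels) of any node is labeled with the curve's id.
A growing end that comes within the claim radius of a seed labeled by a
*different* curve registers a collision: the seed's position is recorded as
a branching point and the end stops. Inside `trace_all`, a foreign seed
triggers only if it also lies within `node_spacing` of its owning curve's
polyline ("anchored"): labels spread a full claim radius sideways, so an
unanchored trigger would record branch points at roughly
`claim_radius / sin(half branch angle)` from the true junction (5–9 voxels
on the 60° Y phantom, versus 1–2 voxels anchored).

Collided ends are cut back by `D = 2 *` (mean estimated radius of the curve;
the working estimate before any contour fit is `R_min`), so that
cross-section contours of the two curves cannot intersect in the branching
region; radius estimation additionally skips nodes within `D` arclength of
any branch point. The loop pops seeds in descending response order until all
are labeled; curves with fewer than 3 nodes are discarded (their seeds stay
consumed). The result is deterministic for fixed inputs.

# Radius estimation: the 2-D sliding band filter

At each node, the local frame takes `v1` as the central-difference unit
tangent, `v2` as the global axis least aligned with `v1` projected onto the
orthogonal plane, and `v3 = v1 × v2`. Along each of `n = 16` in-plane rays,
a band of thickness `d_radius` slides over `(R_min, R_max)` and the boundary
radius `r_k` is the integer band center maximizing the mean VCI toward the
node (ties toward smaller radii; on a flat volume every response is 0 and
the degenerate output is `r_k = R_min + 1`). The boundary points
`center + r_k (cos θ_k v2 + sin θ_k v3)` fit non-circular cross-sections;
larger `n` refines the polygonal fit, though strict monotonicity of the area
error is broken by the integer quantization of `r_k`. The per-node SWC
radius is the mean of the `r_k`.

Two practical constraints matter here, both consequences of the convergence
index being *magnitude-blind* (it sees gradient directions only):

* **Use the unsmoothed gradient.** Gaussian smoothing smears the wall's
  gradient shell; since even infinitesimal gradients carry full VCI weight,
  every band inside the smeared shell saturates at response 1.0 and the
  argmax collapses to the tie rule. Radius estimation therefore uses
  `sigma_g = 0` (`reconstruct_neuron` does this automatically), while
  seeding keeps its smoothed gradient.
* **The filter localizes compact edges.** On a profile that falls smoothly
  to zero (the `"cosine"` phantom), the *entire interior* is one coherent
  convergence region and the wall cannot be localized — the filter was
  derived for objects with a bright, compactly-edged boundary. The
  radius-recovery tests therefore use the `"hard"` profile; on real
  micrographs the point-spread function plus noise produce the compact
  gradient shell the filter expects.

For thin neurites the band is narrowed to `d_radius = min(d, 2 R_min - 1)`
(rounded down to even) so it stays outside the node itself.

# Export

`build_tree` turns each curve into an SWC chain; a curve with a branch hit
is parented at the nearest node of the (earlier) curve it collided with,
attached at its collided end, giving contiguous ids with parents before
children and type code 5 at fork nodes. Coordinates and radii are scaled by
the voxel spacing on write. `loft_mesh` joins adjacent contours of each
curve with quad strips (split into triangles) and fans the two open ends,
yielding a per-curve manifold OBJ surface; branch junctions are left open
for downstream surface interpolation — the full non-parallel contour-network
reconstruction is out of scope and this lofting is deliberately simple
plumbing.

# Evaluation

* `point_deviation`: the mean Euclidean distance from each evaluated point
  to its nearest gold-standard point, with gold centerlines densely
  resampled (0.5-voxel steps). Nearest neighbours come from an exact
  uniform-grid spatial index, tested against all-pairs brute force.
* `precision_recall`: both traces resampled at 0.5-voxel steps; precision is
  the fraction of automated samples within `match_tol` of the gold standard,
  and recall is computed symmetrically from the gold side (the fraction of
  gold samples covered), which avoids rewarding oversampled automated
  traces. The default `match_tol = 2` voxels is exposed because published
  precision/recall values are tolerance-sensitive.
* `skeleton_length`: total polyline arclength of a trace.

# The synthetic phantoms and what a green test establishes

`make_tube`, `make_helix`, `make_y_branch` and `make_elliptic_tube` render
tubes around analytic centerlines with 3× supersampling per axis and box
averaging (thin tubes stay unaliased; profile endpoints land within about
one 8-bit level of their analytic values). Intensities follow either the
smooth `cosine` profile `I = peak cos^2(pi rho / (2r))` or the binary
`hard` profile; `attenuate_signal` scales intensities by `1 - fraction`, and
`add_gaussian_noise` adds i.i.d. normal noise with variance stated on the
`[0, 1]` intensity scale (std `sqrt(v) * 255` on the 8-bit scale), clamped
to `[0, 255]` and reproducible under a fixed seed.

The repository's fixed reference world is `reference_helix()`: a 64³ volume,
helix radius 18, pitch 20, 2 turns, tube radius 4, peak 200, cosine falloff.
The Y phantom defaults to a 60° symmetric fork of radii (5, 4, 4) with limbs
of up to 24 voxels. These sizes were chosen once so that the full filter
support (`rad = 20`) fits the structures and a desk-scale machine traces
them in seconds, and they are not revisited per experiment.

The phantoms emulate tube-like convex regions with controlled radius, signal
attenuation and additive Gaussian noise. They do **not** emulate a
microscope's point-spread function, out-of-focus light, autofluorescent
clutter, varying background, or the densely packed arbors of real image
stacks. A green test on phantoms therefore establishes the *internal*
correctness of each stage (formulas, invariants, parameter recovery,
robustness trends) — not field performance on challenge data sets.

# Numerical choices

* Band range strictness: `r` runs over `{R_min + 1, ..., R_max - 1}`
  (literal strict inequalities); ties toward smaller `r`.
* Flat-gradient cutoff `1e-6` (intensity units/voxel) for the VCI; trilinear
  interpolation everywhere off-grid; zero padding outside the volume.
* Hessians by Gaussian-derivative windows, exact on quadratics; eigenvector
  signs fixed by making each vector's largest component positive.
* The semi-implicit solve uses a dense LU factorization; snakes here are a
  few hundred nodes at most.
* Determinism: the only random stage is phantom noise, controlled by an
  explicit seed; seeding, tracing and radius estimation are deterministic
  given inputs, with all ties broken lexicographically.

# Known limitations

* The seed-label collision scheme records branch points at seed resolution;
  junction geometry below the seed spacing (~2 voxels) is not resolved.
* Radius estimates are integer-valued per ray (no sub-band optimization),
  biasing thin-tube radii by up to ~0.5 voxel and mesh volumes by ~10%.
* The tracer assumes bright tubes on dark background (fluorescence-style
  contrast); bright-field data would at minimum need a larger `R_min`.
* Junction surfaces are left open by the mesh lofting.
* No multiscale filtering: structures much thicker than `R_max` (e.g. large
  somata) need explicitly larger support parameters.
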