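# svftrace

Automatic reconstruction of neuron anatomy from 3-D grayscale microscopy
stacks, for neuroanatomists and bio-image analysts who need centerline trees,
per-branch radii and surface models without manual seeding or editing.

The pipeline has four stages:

1. **Seed detection** with a 3-D convergence-index filter, the *sliding
   volume filter* (SVF). The voxel convergence index at a sample `P` relative
   to a center `O` is `cos φ`, the cosine of the angle between the image
   gradient at `P` and the direction `P → O`. The SVF at a voxel `O` is

   ```
   SVF(O) = (1/M) Σ_{a,b}  max_{R_min < r < R_max}  (1/(d+1)) Σ_{ρ = r-d/2}^{r+d/2} VCI(O + ρ·u(a,b))
   ```

   over `M = 2L²` spherical directions `u(a, b)`: for each direction a band
   of thickness `d` slides along the ray to the radius of maximal mean
   gradient convergence. The response is high on centerlines of tube-like
   bright structures. Voxels above a threshold `T` are refined with a
   Hessian ridge criterion (the in-plane directional derivatives
   `ev₂·∇I`, `ev₃·∇I` must vanish to within the grid's resolution) and kept
   as a response-sorted seed list.

2. **Tracing** with open-curve snakes: curves `c(s)` minimizing
   `∫ α|c_s|² + β|c_ss|² ds + E_image + E_stretch`, deformed by the
   semi-implicit update `x_t = (γI + A)⁻¹(γ x_{t-1} + F)` where `F` is the
   normalized gradient vector flow of the SVF-enhanced volume
   (`I_SVF = 15·√(min(I·(1+SVF), 255))`) plus a tangential stretch force of
   tubeness magnitude `|√|λ₂λ₃|/(|λ₁|+0.01) − 1|` at the two ends. Curves
   grow bidirectionally from seeds, claim nearby seeds with their id, stop
   at another curve's labeled seed (recorded as a branch point), and back
   off by twice their mean radius so cross-section contours cannot collide.

3. **Radius estimation** per node with a 2-D sliding band filter: `n` rays
   in the plane orthogonal to the local tangent each slide a band to the
   radius of maximal gradient convergence toward the node, giving `n`
   boundary points of the (generally non-circular) cross-section.

4. **Export and evaluation**: standard SWC morphology trees, a simple
   contour-lofted OBJ mesh, mean point deviation
   `D(P_s, P_g) = (1/N) Σ_{p∈P_s} d_min(p, P_g)` and length-based
   precision/recall against ground-truth centerlines.

A synthetic-phantom module (straight/curved/elliptical tubes, helices,
Y-branches, with controlled radius, signal attenuation and Gaussian noise)
makes the whole pipeline testable offline; see the methods vignette
(`vignettes/svftrace-methods.Rmd`) for the model, parameter and numerical
details.

## Worked example

Trace the package's reference phantom — a 2-turn helical tube (radius 4
voxels, peak intensity 200) in a 64³ volume — and score the result against
the analytic centerline:

```r
library(svftrace)

phantom <- reference_helix()
phantom
#> <phantom> 461 centerline samples, radius [4.00, 4.00], 0 branch point(s)
#> <svf_volume> 64 x 64 x 64 voxels, intensity [0.00, 194.41], spacing (1, 1, 1)

res <- reconstruct_neuron(phantom$volume)
res$trace
#> <neuron_trace> 1 curve(s), total length 234.6 voxels, 0 branch point(s)

precision_recall(res$trace, list(phantom$centerline), match_tol = 2)
#> <trace_match> precision 0.994, recall 1.000 (tol 2 voxels; auto 235.5 / gold 230.5 voxels)

point_deviation(res$seeds, resample_polyline(phantom$centerline, 0.5))
#> [1] 1.6065
```

The tracer recovers the helix as a single curve: 99.4% of the traced length
lies within 2 voxels of the true centerline, the full centerline is covered,
and the 346 detected seeds sit on average 1.61 voxels from it.

Cross-section radii are estimated on the unsmoothed gradient (the band
filter localizes compact gradient shells; see the vignette):

```r
tube <- make_tube(rbind(c(8, 32, 32), c(56, 32, 32)), radius = 5,
                  falloff = "hard")
grad <- compute_gradient(tube$volume, sigma_g = 0)
frame <- local_frame(resample_polyline(tube$centerline, 2), 7)
sbf_boundary(grad, c(32, 32, 32), frame, n = 16,
             filter_params(rad = 20, d = 4, r_min = 2, r_max = 12))
#> <sbf_contour> 16 boundary points, radii [4.0, 5.0], mean 4.75
```

The 16 boundary radii bracket the true radius 5 within one voxel.

Stacks on disk are handled with `load_stack()` / `save_stack()` (multi-page
TIFF or a directory of slices), morphologies with `write_swc()` /
`read_swc()`, meshes with `loft_mesh()`. A command-line front end over the
same functions lives at `inst/cli/svftrace.R`:

```sh
Rscript inst/cli/svftrace.R phantom --kind helix -o helix.tif --truth truth.swc
Rscript inst/cli/svftrace.R trace helix.tif -o trace.swc
Rscript inst/cli/svftrace.R eval --auto trace.swc --gold truth.swc --tol 2
```

## Benchmark script

`scripts/acceptance.R` regenerates the reference helix from scratch, runs
SVF seeding with the canonical parameters (`rad = 20`, `d = 8`, `L = 20`,
`R_min = 5`, `R_max = 16`, `T = 0.7`), and writes the mean point deviation
of the final seeds from the analytic centerline (plus the seed count) as
JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The seeding pipeline is deterministic; the seed argument only controls RNG
state hygiene.
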