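# Convergence-index machinery: the voxel convergence index (VCI), radial band
# responses, the 3-D sliding volume filter (SVF) and SVF volume enhancement.
#
# The VCI at a sample P relative to a center O is the cosine of the angle
# between the image gradient at P and the direction P -> O: +1 when gradients
# converge exactly on O, 0 for flat regions, -1 when they point away. The SVF
# averages, over a spherical grid of M = 2 L^2 directions, the best radial
# band (thickness d, center sliding in the strict integer range
# (R_min, R_max)) of VCIs, which is high at tube centerlines.

#' Sliding-filter parameters
#'
#' Parameters shared by the 3-D sliding volume filter (seeding) and the 2-D
#' sliding band filter (radius estimation). The band must stay inside the
#' support region: `d/2 <= r_min < r_max <= rad - d/2`. The band center
#' slides over the strict integer range `(r_min, r_max)`, i.e.
#' `{r_min + 1, ..., r_max - 1}`, with ties broken toward smaller radii.
#'
#' @param rad support-region radius (voxels).
#' @param d band/volume thickness (voxels, even, >= 2); band samples sit at
#'   the `d + 1` integer radial offsets in `[r - d/2, r + d/2]`.
#' @param L angular resolution: the azimuth is divided into `2L` parts and
#'   the polar angle into `L` parts, giving `M = 2 L^2` directions.
#' @param r_min,r_max sliding range of the band center (voxels).
#' @param T seed-response threshold in `(-1, 1)`.
#' @return An object of class `svf_filter_params`.
#' @export
filter_params <- function(rad = 20, d = 8, L = 20, r_min = 5,
                          r_max = rad - d / 2, T = 0.7) {
  if (d < 2 || d %% 2 != 0) stop("`d` must be an even integer >= 2")
  if (L < 4) stop("`L` must be >= 4")
  if (T <= -1 || T >= 1) stop("`T` must lie in (-1, 1)")
  if (!(d / 2 <= r_min && r_min < r_max && r_max <= rad - d / 2))
    stop("need d/2 <= r_min < r_max <= rad - d/2 (band inside support region)")
  if (r_max - 1 < r_min + 1)
    stop("empty band-center range: need r_min + 1 <= r_max - 1")
  structure(list(rad = rad, d = as.integer(d), L = as.integer(L),
                 r_min = as.integer(r_min), r_max = as.integer(r_max), T = T),
            class = "svf_filter_params")
}

#' @export
print.svf_filter_params <- function(x, ...) {
  cat(sprintf("<svf_filter_params> rad=%g d=%d L=%d (M=%d) r in (%d, %d), T=%g\n",
              x$rad, x$d, x$L, 2L * x$L^2, x$r_min, x$r_max, x$T))
  invisible(x)
}

#' Spherical direction grid
#'
#' The `M = 2 L^2` unit vectors `u(a, b) = (sin b cos a, sin b sin a, cos b)`
#' with `a = pi i / L` (`i = 0, ..., 2L - 1`) and `b = pi j / L`
#' (`j = 0, ..., L - 1`). The grid double-covers directions near the poles by
#' construction; no area weighting is applied.
#'
#' @param L angular resolution.
#' @return An `M x 3` matrix of unit vectors.
#' @export
direction_grid <- function(L) {
  a <- pi * (0:(2 * L - 1)) / L
  b <- pi * (0:(L - 1)) / L
  g <- expand.grid(a = a, b = b)
  cbind(sin(g$b) * cos(g$a), sin(g$b) * sin(g$a), cos(g$b))
}

#' Image gradient field
#'
#' Gaussian-smoothed central-difference gradient of a volume: the volume is
#' smoothed at scale `sigma_g` (separable, replicate borders), then
#' differentiated with central differences (one-sided at the borders).
#' `sigma_g = 0` gives plain central differences.
#'
#' @param volume an `svf_volume`.
#' @param sigma_g smoothing scale in voxels (>= 0; default 2: half the
#'   radius of the thinnest structure of interest).
#' @return A `gradient_field`: arrays `gx`, `gy`, `gz` plus `sigma_g`.
#' @export
compute_gradient <- function(volume, sigma_g = 2) {
  assert_volume(volume)
  if (sigma_g < 0) stop("`sigma_g` must be >= 0")
  sm <- if (sigma_g > 0) cpp_gaussian_smooth(volume$data, sigma_g)
        else volume$data
  g <- cpp_central_gradient(sm)
  structure(list(gx = g$gx, gy = g$gy, gz = g$gz, sigma_g = sigma_g),
            class = "gradient_field")
}

assert_gradient <- function(x) {
  if (!inherits(x, "gradient_field"))
    stop("expected a `gradient_field` (see `compute_gradient()`)")
  invisible(x)
}

# Trilinear gradient samples at an m x 3 matrix of points.
sample_gradient <- function(grad, pts) {
  cpp_sample_vec3(grad$gx, grad$gy, grad$gz, as_pts_matrix(pts))
}

as_pts_matrix <- function(pts) {
  m <- if (is.matrix(pts)) pts else matrix(pts, ncol = 3, byrow = TRUE)
  storage.mode(m) <- "double"
  m
}

#' Voxel convergence index
#'
#' Cosine of the angle between the gradient at `P` (trilinear) and the
#' direction from `P` to `O`; 0 where the gradient is flat
#' (magnitude < 1e-6).
#'
#' @param grad a `gradient_field`.
#' @param O reference point (length 3, 0-based voxel coordinates).
#' @param P sample point, distinct from `O`.
#' @return A scalar in `[-1, 1]`.
#' @export
vci <- function(grad, O, P) {
  assert_gradient(grad)
  O <- as.numeric(O); P <- as.numeric(P)
  po <- O - P
  npo <- sqrt(sum(po^2))
  if (npo < 1e-12) stop("`O` and `P` must be distinct points")
  g <- sample_gradient(grad, P)[1, ]
  ng <- sqrt(sum(g^2))
  if (ng < 1e-6) return(0)
  sum(g * po) / (ng * npo)
}

#' Radial band response
#'
#' Mean VCI over the `d + 1` integer radial offsets `rho` in
#' `[r - d/2, r + d/2]` at positions `O + rho * u`, with the convergence
#' measured toward `O`. Samples falling outside the volume contribute 0.
#'
#' @param grad a `gradient_field`.
#' @param O band center origin (length 3).
#' @param u unit direction (length 3).
#' @param r band-center radius (voxels); requires `r - d/2 >= 1`.
#' @param d band thickness (even).
#' @return A scalar in `[-1, 1]`.
#' @export
band_response <- function(grad, O, u, r, d) {
  assert_gradient(grad)
  if (r - d / 2 < 1) stop("band extends inside the center: need r - d/2 >= 1")
  rho <- seq(r - d / 2, r + d / 2)
  pts <- outer(rho, as.numeric(u)) + matrix(O, nrow = length(rho), ncol = 3,
                                            byrow = TRUE)
  g <- sample_gradient(grad, pts)
  ng <- sqrt(rowSums(g^2))
  # direction from sample toward O is -u; flat samples contribute 0
  v <- ifelse(ng < 1e-6, 0, -(g %*% as.numeric(u))[, 1] / pmax(ng, 1e-300))
  mean(v)
}

#' Sliding volume filter response at one point
#'
#' `SVF(O) = (1/M) * sum over the M grid directions of the maximum band
#' response over integer band centers r in (r_min, r_max)`.
#'
#' @param grad a `gradient_field`.
#' @param O evaluation point (length 3, 0-based; may be off-grid).
#' @param params an [filter_params()] object.
#' @return A scalar in `[-1, 1]`.
#' @export
svf_at <- function(grad, O, params) {
  assert_gradient(grad)
  stopifnot(inherits(params, "svf_filter_params"))
  dirs <- direction_grid(params$L)
  cpp_svf_at(grad$gx, grad$gy, grad$gz, dirs, as.numeric(O),
             params$r_min, params$r_max, params$d)
}

#' Sliding volume filter response volume
#'
#' Evaluates the SVF at every voxel with intensity >= `mask_floor`; all other
#' voxels get response -1 (they can never become seeds). Deterministic.
#'
#' @param volume an `svf_volume`.
#' @param params an [filter_params()] object.
#' @param mask_floor minimum intensity for evaluation (default 1: skip pure
#'   background for speed; correctness above the floor is unchanged).
#' @param grad optional precomputed `gradient_field`; computed at
#'   `sigma_g = 2` when missing.
#' @return An `svf_response`: array `data` in `[-1, 1]` plus the parameters.
#' @export
svf_volume <- function(volume, params, mask_floor = 1, grad = NULL) {
  assert_volume(volume)
  stopifnot(inherits(params, "svf_filter_params"))
  if (is.null(grad)) grad <- compute_gradient(volume, sigma_g = 2)
  assert_gradient(grad)
  mask <- volume$data >= mask_floor
  dirs <- direction_grid(params$L)
  resp <- cpp_svf_volume(grad$gx, grad$gy, grad$gz, mask, dirs,
                         params$r_min, params$r_max, params$d)
  structure(list(data = resp, params = params, mask_floor = mask_floor),
            class = "svf_response")
}

#' @export
print.svf_response <- function(x, ...) {
  cat(sprintf("<svf_response> %s voxels, response [%.3f, %.3f]\n",
              paste(dim(x$data), collapse = " x "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' SVF volume enhancement
#'
#' Remaps intensities as `I_svf(p) = 15 * sqrt(min(I(p) * (1 + SVF(p)), 255))`
#' with negative inner products clamped to 0 before the square root. This
#' brightens voxels whose surroundings converge on them (centerlines) and
#' compresses the dynamic range, which smooths the gradient-vector-flow field
#' used by the snake tracer.
#'
#' @param volume an `svf_volume`.
#' @param response an `svf_response` aligned with `volume`.
#' @return An `svf_volume` with intensities in `[0, 15 * sqrt(255)]`.
#' @export
enhance_volume <- function(volume, response) {
  assert_volume(volume)
  stopifnot(inherits(response, "svf_response"))
  if (!all(dim(volume$data) == dim(response$data)))
    stop("response is not aligned with the volume")
  inner <- pmin(pmax(volume$data * (1 + response$data), 0), 255)
  as_volume(15 * sqrt(inner), volume$spacing)
}
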