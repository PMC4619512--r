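# Synthetic tubular phantoms: ground-truthed test volumes for every stage of
# the pipeline. Rendering is supersampled (3x per axis, box-averaged) to avoid
# aliasing of thin tubes; the "cosine" profile is
#   I(rho) = peak * cos^2(pi * rho / (2 r))   for rho <= r, else 0,
# so intensity is maximal on the centerline and falls smoothly to zero at the
# tube wall; "hard" is a binary disk (flat core, compact edge).

PROFILE_IDS <- c(cosine = 0L, hard = 1L)
SUPERSAMPLE <- 3L

new_phantom <- function(volume, centerline, radius_profile,
                        branch_points = NULL, gold = NULL) {
  shape <- vol_shape(volume)
  if (nrow(centerline) < 1) stop("empty centerline")
  lo <- apply(centerline, 2, min); hi <- apply(centerline, 2, max)
  if (any(lo < 0) || any(hi > shape - 1))
    stop("centerline exits the volume bounds")
  if (any(radius_profile <= 0) || any(radius_profile >= min(shape) / 2))
    stop("radius profile must be positive and below min(shape)/2")
  structure(list(volume = volume, centerline = centerline,
                 radius_profile = radius_profile,
                 branch_points = branch_points,
                 gold = if (is.null(gold)) list(centerline) else gold),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d centerline samples, radius [%.2f, %.2f], %d branch point(s)\n",
              nrow(x$centerline), min(x$radius_profile), max(x$radius_profile),
              if (is.null(x$branch_points)) 0L else nrow(x$branch_points)))
  print(x$volume)
  invisible(x)
}

#' Resample a polyline at a fixed arclength step
#'
#' Linear interpolation along the polyline at steps of at most `step` voxels,
#' keeping both endpoints. Used to densify centerlines for the evaluation
#' metrics.
#'
#' @param pts an `m x 3` point matrix.
#' @param step arc step in voxels.
#' @return A resampled point matrix.
#' @export
resample_polyline <- function(pts, step = 0.5) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 2) return(pts)
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                       pts[-nrow(pts), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total == 0) return(pts[1, , drop = FALSE])
  s <- seq(0, total, by = step)
  if (total - s[length(s)] > 1e-9) s <- c(s, total)
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx <- pmin(idx, nrow(pts) - 1)
  frac <- (s - cum[idx]) / pmax(seg[idx], 1e-12)
  pts[idx, , drop = FALSE] +
    (pts[idx + 1, , drop = FALSE] - pts[idx, , drop = FALSE]) * frac
}

polyline_length <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                    pts[-nrow(pts), , drop = FALSE])^2)))
}

render_centerline <- function(centerline, radii, peak, falloff, shape) {
  pts <- as.matrix(centerline)
  n <- nrow(pts)
  segs <- cbind(pts[-n, , drop = FALSE], pts[-1, , drop = FALSE],
                radii[-n], radii[-1])
  data <- cpp_render_tubes(as.integer(shape), segs, peak,
                           PROFILE_IDS[[falloff]], SUPERSAMPLE)
  as_volume(clamp255(data))
}

#' Generate a tubular phantom along an arbitrary centerline
#'
#' @param centerline either an m x 3 matrix of 0-based voxel coordinates or a
#'   function of a parameter in `[0, 1]` returning a length-3 point; function
#'   curves are sampled densely and resampled to <= 0.5-voxel arc steps.
#' @param radius tube radius in voxels (>= 2): a scalar, or a function of
#'   arclength (voxels from the start of the curve).
#' @param peak_intensity intensity on the centerline (8-bit scale).
#' @param falloff `"cosine"` (smooth, default) or `"hard"` (binary disk).
#' @param shape volume dimensions `(nx, ny, nz)`.
#' @return A `phantom`: the rendered volume plus ground-truth centerline,
#'   per-sample radius profile and (empty) branch-point registry.
#' @export
make_tube <- function(centerline, radius, peak_intensity = 200,
                      falloff = c("cosine", "hard"), shape = c(64, 64, 64)) {
  falloff <- match.arg(falloff)
  if (is.function(centerline)) {
    t0 <- seq(0, 1, length.out = 256)
    pts <- t(vapply(t0, centerline, numeric(3)))
    pts <- resample_polyline(pts, 0.5)
  } else {
    pts <- resample_polyline(as.matrix(centerline), 0.5)
  }
  arc <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  radii <- if (is.function(radius)) vapply(arc, radius, numeric(1))
           else rep(radius, nrow(pts))
  if (any(radii < 2)) stop("tube radius must be >= 2 voxels")
  vol <- render_centerline(pts, radii, peak_intensity, falloff, shape)
  new_phantom(vol, pts, radii)
}

#' Generate a straight tube with an elliptical cross-section
#'
#' A straight tube from `p1` to `p2` whose cross-section is an ellipse with
#' semi-axes `semi_axes = c(a, b)`; used to exercise the sliding-band radius
#' estimator on non-circular neurites.
#'
#' @param p1,p2 tube endpoints (0-based voxel coordinates).
#' @param semi_axes ellipse semi-axes `(a, b)` in voxels, both >= 2.
#' @param peak_intensity,falloff,shape as in [make_tube()].
#' @return A `phantom`; `radius_profile` carries the mean semi-axis.
#' @export
make_elliptic_tube <- function(p1, p2, semi_axes, peak_intensity = 200,
                               falloff = c("cosine", "hard"),
                               shape = c(64, 64, 64)) {
  falloff <- match.arg(falloff)
  if (any(semi_axes < 2)) stop("semi-axes must be >= 2 voxels")
  axis <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  n1 <- ref - sum(ref * axis) * axis
  n1 <- n1 / sqrt(sum(n1^2))
  n2 <- c(axis[2] * n1[3] - axis[3] * n1[2],
          axis[3] * n1[1] - axis[1] * n1[3],
          axis[1] * n1[2] - axis[2] * n1[1])
  data <- cpp_render_elliptic_tube(as.integer(shape), p1, p2, n1, n2,
                                   semi_axes[1], semi_axes[2], peak_intensity,
                                   PROFILE_IDS[[falloff]], SUPERSAMPLE)
  vol <- as_volume(clamp255(data))
  pts <- resample_polyline(rbind(p1, p2), 0.5)
  new_phantom(vol, pts, rep(mean(semi_axes), nrow(pts)))
}

#' Generate a helical tube phantom
#'
#' The helix axis runs along z through the volume center; the analytic
#' centerline is sampled at <= 1-voxel arc steps (0.5 used).
#'
#' @param helix_radius radius of the helix (voxels).
#' @param pitch z rise per full turn (voxels).
#' @param turns number of turns (> 0).
#' @param tube_radius tube radius (voxels, >= 2).
#' @param shape volume dimensions.
#' @param peak_intensity,falloff as in [make_tube()].
#' @return A `phantom`.
#' @export
make_helix <- function(helix_radius = 18, pitch = 20, turns = 2,
                       tube_radius = 4, shape = c(64, 64, 64),
                       peak_intensity = 200,
                       falloff = c("cosine", "hard")) {
  falloff <- match.arg(falloff)
  if (turns <= 0) stop("`turns` must be > 0 (degenerate empty curve)")
  if (tube_radius < 2) stop("tube radius must be >= 2 voxels")
  ctr <- (shape - 1) / 2
  height <- turns * pitch
  margin <- tube_radius + 1
  if (helix_radius + margin > min(ctr[1], ctr[2]) ||
      height / 2 + margin > ctr[3])
    stop("helix does not fit inside the volume with the tube-radius margin")
  speed <- sqrt(helix_radius^2 + (pitch / (2 * pi))^2)
  t_end <- 2 * pi * turns
  n <- max(2L, ceiling(speed * t_end / 0.5) + 1L)
  tt <- seq(0, t_end, length.out = n)
  pts <- cbind(ctr[1] + helix_radius * cos(tt),
               ctr[2] + helix_radius * sin(tt),
               ctr[3] - height / 2 + pitch * tt / (2 * pi))
  vol <- render_centerline(pts, rep(tube_radius, n), peak_intensity, falloff,
                           shape)
  new_phantom(vol, pts, rep(tube_radius, n))
}

#' The reference helix phantom
#'
#' The repository's fixed reference object: a 64^3 volume holding a 2-turn
#' helix (helix radius 18, pitch 20) of tube radius 4, peak intensity 200,
#' cosine falloff. All scaled-down benchmark experiments in the package run
#' against this phantom.
#'
#' @return A `phantom`.
#' @export
reference_helix <- function() {
  make_helix(helix_radius = 18, pitch = 20, turns = 2, tube_radius = 4,
             shape = c(64, 64, 64), peak_intensity = 200, falloff = "cosine")
}

#' Generate a Y-branch phantom
#'
#' A trunk along `trunk_dir` meeting two symmetric daughter branches at a
#' junction placed at the volume center; branch directions are obtained by
#' rotating the trunk direction by `+/- branch_angle / 2` in a fixed plane.
#' The volume is the voxelwise maximum of the three tube fields.
#'
#' @param trunk_dir direction of the trunk (length-3, need not be unit).
#' @param branch_angle angle between the two daughter branches, degrees,
#'   strictly inside (0, 180).
#' @param radii radii `(r_trunk, r_branch1, r_branch2)`, all >= 2.
#' @param shape volume dimensions.
#' @param limb_length length of each limb in voxels (trimmed to fit bounds).
#' @param peak_intensity,falloff as in [make_tube()].
#' @return A `phantom` with one `branch_points` entry at the junction and
#'   `gold` holding the three limb polylines.
#' @export
make_y_branch <- function(trunk_dir = c(1, 0, 0), branch_angle = 60,
                          radii = c(5, 4, 4), shape = c(64, 64, 64),
                          limb_length = 24, peak_intensity = 200,
                          falloff = c("cosine", "hard")) {
  falloff <- match.arg(falloff)
  if (branch_angle <= 0 || branch_angle >= 180)
    stop("`branch_angle` must lie strictly between 0 and 180 degrees")
  if (any(radii < 2)) stop("radii must be >= 2 voxels")
  u <- trunk_dir / sqrt(sum(trunk_dir^2))
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w <- ref - sum(ref * u) * u
  w <- w / sqrt(sum(w^2))
  half <- branch_angle / 2 * pi / 180
  b1 <- cos(half) * u + sin(half) * w
  b2 <- cos(half) * u - sin(half) * w
  junction <- (shape - 1) / 2
  if (any(junction <= 1) || any(junction >= shape - 2))
    stop("branch point must be interior to the volume")

  fit_len <- function(dir, margin) {
    # largest t with junction + t*dir at least `margin` from every face
    lims <- vapply(1:3, function(i) {
      if (abs(dir[i]) < 1e-12) return(Inf)
      if (dir[i] > 0) (shape[i] - 1 - margin - junction[i]) / dir[i]
      else (margin - junction[i]) / dir[i]
    }, numeric(1))
    max(0, min(lims, limb_length))
  }
  l0 <- fit_len(-u, radii[1] + 1)
  l1 <- fit_len(b1, radii[2] + 1)
  l2 <- fit_len(b2, radii[3] + 1)
  if (min(l0, l1, l2) < 4) stop("volume too small for the requested Y-branch")
  limbs <- list(
    resample_polyline(rbind(junction - l0 * u, junction), 0.5),
    resample_polyline(rbind(junction, junction + l1 * b1), 0.5),
    resample_polyline(rbind(junction, junction + l2 * b2), 0.5))
  limb_radii <- rep(radii, vapply(limbs, nrow, integer(1)))
  all_pts <- do.call(rbind, limbs)
  n_each <- vapply(limbs, nrow, integer(1))
  segs <- do.call(rbind, lapply(1:3, function(i) {
    p <- limbs[[i]]; m <- nrow(p)
    cbind(p[-m, , drop = FALSE], p[-1, , drop = FALSE],
          rep(radii[i], m - 1), rep(radii[i], m - 1))
  }))
  data <- cpp_render_tubes(as.integer(shape), segs, peak_intensity,
                           PROFILE_IDS[[falloff]], SUPERSAMPLE)
  vol <- as_volume(clamp255(data))
  new_phantom(vol, all_pts, limb_radii,
              branch_points = matrix(junction, nrow = 1), gold = limbs)
}

#' Attenuate a volume's signal
#'
#' Scales every intensity by `1 - fraction`, emulating signal loss from
#' unbalanced illumination.
#'
#' @param volume an `svf_volume`.
#' @param fraction fraction of signal removed, in `[0, 1)`.
#' @return An `svf_volume`.
#' @export
attenuate_signal <- function(volume, fraction) {
  assert_volume(volume)
  if (fraction < 0 || fraction >= 1)
    stop("`fraction` must lie in [0, 1)")
  as_volume(clamp255(volume$data * (1 - fraction)), volume$spacing)
}

#' Add Gaussian noise to a volume
#'
#' Noise is i.i.d. normal with the given variance on the unit intensity scale
#' `[0, 1]` (so its standard deviation on the 8-bit scale is
#' `sqrt(variance) * 255`), then the result is clamped to `[0, 255]`.
#' Reproducible under a fixed `seed`.
#'
#' @param volume an `svf_volume`.
#' @param variance noise variance on the `[0, 1]` scale (e.g. 0.01--0.04).
#' @param seed integer RNG seed.
#' @return An `svf_volume`.
#' @export
add_gaussian_noise <- function(volume, variance, seed = 0L) {
  assert_volume(volume)
  if (variance < 0) stop("`variance` must be >= 0")
  if (variance == 0) return(volume)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  noise <- stats::rnorm(length(volume$data), 0, sqrt(variance) * 255)
  as_volume(clamp255(volume$data + noise), volume$spacing)
}
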