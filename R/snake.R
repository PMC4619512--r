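# Open-curve snake primitives: parameter container, the internal (smoothness)
# operator, the endpoint stretch force, semi-implicit deformation, and curve
# initialization from a seed.

#' Open-curve snake parameters
#'
#' @param alpha elasticity weight (> 0): penalizes stretching.
#' @param beta stiffness weight (>= 0): penalizes bending; forced to 0 at the
#'   two end nodes (the ends are driven by the stretch force instead).
#' @param gamma step control of the semi-implicit update (> 0); larger values
#'   take smaller steps.
#' @param t_max maximum deformation iterations per call (>= 1).
#' @param extend_step voxels appended per extension, in `(0, 3]`.
#' @param node_spacing resampling interval in voxels; consecutive node
#'   distances stay within `[0.5, 2] * node_spacing`.
#' @param stretch_eps convergence threshold on the endpoint stretch magnitude.
#' @param claim_radius radius (voxels) within which a curve claims seeds;
#'   `NULL` (default) uses `max(2, mean radius of the curve)`.
#' @param backoff_factor multiplier on the mean estimated radius giving the
#'   cut-back length `D` at collided ends (default 2: twice the mean radius).
#' @param stretch_cap cap on the applied stretch-force magnitude (the raw
#'   tubeness magnitude can be arbitrarily large at a perfect centerline;
#'   forces are unit-scale like the normalized flow field).
#' @param bg_floor intensity below which an end node is considered to be in
#'   background; an end that stays in background converges.
#' @param max_extensions safety bound on extensions per curve.
#' @return An object of class `snake_params`.
#' @export
snake_params <- function(alpha = 0.8, beta = 0.2, gamma = 2, t_max = 10,
                         extend_step = 1.5, node_spacing = 1.5,
                         stretch_eps = 0.2, claim_radius = NULL,
                         backoff_factor = 2, stretch_cap = 1,
                         bg_floor = 1, max_extensions = 400) {
  if (alpha <= 0 || gamma <= 0) stop("`alpha` and `gamma` must be > 0")
  if (beta < 0) stop("`beta` must be >= 0")
  if (t_max < 1) stop("`t_max` must be >= 1")
  if (extend_step <= 0 || extend_step > 3)
    stop("`extend_step` must lie in (0, 3]")
  if (node_spacing <= 0) stop("`node_spacing` must be > 0")
  if (backoff_factor <= 0) stop("`backoff_factor` must be > 0")
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 t_max = as.integer(t_max), extend_step = extend_step,
                 node_spacing = node_spacing, stretch_eps = stretch_eps,
                 claim_radius = claim_radius,
                 backoff_factor = backoff_factor, stretch_cap = stretch_cap,
                 bg_floor = bg_floor,
                 max_extensions = as.integer(max_extensions)),
            class = "snake_params")
}

new_snake_curve <- function(id, nodes) {
  structure(list(id = as.integer(id), nodes = nodes,
                 state = c(head = "growing", tail = "growing"),
                 branch_hits = data.frame(x = numeric(), y = numeric(),
                                          z = numeric(), other = integer()),
                 mean_radius = NA_real_,
                 stretch_ok = c(head = 0L, tail = 0L),
                 bg_count = c(head = 0L, tail = 0L),
                 end_hist = list(head = list(), tail = list())),
            class = "snake_curve")
}

#' @export
print.snake_curve <- function(x, ...) {
  cat(sprintf("<snake_curve #%d> %d nodes, length %.1f, head %s / tail %s, %d branch hit(s)\n",
              x$id, nrow(x$nodes), polyline_length(x$nodes),
              x$state["head"], x$state["tail"], nrow(x$branch_hits)))
  invisible(x)
}

#' Internal smoothness operator of an open snake
#'
#' The pentadiagonal matrix `A` discretizing `alpha * (-c_ss) + beta * c_ssss`
#' with free (open-curve) boundary conditions. The two end rows are zero --
#' the stiffness weight vanishes at the endpoints and the ends are driven by
#' the stretch force -- so `A` annihilates straight evenly spaced curves (no
#' artificial shrinkage) and all its eigenvalues are real and >= 0.
#'
#' @param n_nodes number of snake nodes (>= 3).
#' @param params a [snake_params()] object (uses `alpha`, `beta`).
#' @param spacing node spacing `h` used in the difference quotients.
#' @return An `n x n` matrix.
#' @export
internal_matrix <- function(n_nodes, params, spacing = params$node_spacing) {
  n <- as.integer(n_nodes)
  if (n < 3) stop("a snake needs at least 3 nodes")
  h <- spacing
  d1 <- diff(diag(n))                      # (n-1) x n first differences
  d2 <- diff(diag(n), differences = 2)     # (n-2) x n second differences
  A <- params$alpha * crossprod(d1) / h^2 +
       params$beta * crossprod(d2) / h^4
  A[1, ] <- 0
  A[n, ] <- 0
  A
}

# Raw tubeness-based stretch magnitude |sqrt(|l2 l3|) / (|l1| + 0.01) - 1|
# from the ordered Hessian eigenvalues.
stretch_magnitude <- function(values) {
  abs(sqrt(abs(values[2] * values[3])) / (abs(values[1]) + 0.01) - 1)
}

#' Endpoint stretch force
#'
#' The force that elongates a snake along its own tangent: direction is the
#' outward unit tangent at the chosen end, magnitude is the tubeness measure
#' `| sqrt(|lambda2 lambda3|) / (|lambda1| + 0.01) - 1 |` of the Hessian at
#' the end node. On a tube the magnitude is much larger than 1 (the end keeps
#' growing); at a blob-like neurite terminal the eigenvalues become
#' comparable and the magnitude drops toward 0, which stops the growth. A
#' magnitude below `stretch_eps` returns the zero vector.
#'
#' @param curve a `snake_curve` with >= 2 nodes.
#' @param end `"head"` (first node) or `"tail"` (last node).
#' @param volume the `svf_volume` in which tubeness is measured.
#' @param sigma_h Hessian scale (voxels).
#' @param stretch_eps zero-force threshold (default 0.2).
#' @return A length-3 force vector with attribute `"magnitude"` (the raw
#'   tubeness magnitude, before thresholding).
#' @export
stretch_force <- function(curve, end = c("head", "tail"), volume,
                          sigma_h = 1.5, stretch_eps = 0.2) {
  end <- match.arg(end)
  nodes <- curve$nodes
  n <- nrow(nodes)
  if (n < 2) stop("curve must have at least 2 nodes")
  tang <- if (end == "head") nodes[1, ] - nodes[2, ]
          else nodes[n, ] - nodes[n - 1, ]
  nt <- sqrt(sum(tang^2))
  if (nt < 1e-9) stop("degenerate tangent: coincident end nodes")
  tang <- tang / nt
  p <- if (end == "head") nodes[1, ] else nodes[n, ]
  shape <- vol_shape(volume)
  p <- pmin(pmax(p, 0), shape - 1)
  hi <- hessian_at(volume, p, sigma_h)
  mag <- stretch_magnitude(hi$values)
  force <- if (mag < stretch_eps) c(0, 0, 0) else tang * mag
  attr(force, "magnitude") <- mag
  force
}

clamp_nodes <- function(nodes, shape) {
  nodes[, 1] <- pmin(pmax(nodes[, 1], 0), shape[1] - 1)
  nodes[, 2] <- pmin(pmax(nodes[, 2], 0), shape[2] - 1)
  nodes[, 3] <- pmin(pmax(nodes[, 3], 0), shape[3] - 1)
  nodes
}

#' Deform a snake under the flow field
#'
#' Runs up to `t_max` semi-implicit steps
#' `x_t = (gamma I + A)^{-1} (gamma x_{t-1} + F(x_{t-1}))` per coordinate,
#' where `F` is the (unit) flow field sampled trilinearly at every node plus
#' the endpoint stretch force (capped at `stretch_cap`) at the two end nodes.
#' Nodes are clamped to the volume bounds; the curve is resampled to
#' `node_spacing` after the loop.
#'
#' @param curve a `snake_curve`.
#' @param flow a `flow_field` aligned with `volume`.
#' @param volume the `svf_volume` used for the stretch force.
#' @param params a [snake_params()] object.
#' @param sigma_h Hessian scale for the stretch force.
#' @param stretch apply the endpoint stretch force (TRUE by default).
#' @return The deformed `snake_curve`.
#' @export
deform_curve <- function(curve, flow, volume, params, sigma_h = 1.5,
                         stretch = TRUE) {
  nodes <- curve$nodes
  n <- nrow(nodes)
  if (n < 3) stop("curve must have at least 3 nodes")
  shape <- vol_shape(volume)
  A <- internal_matrix(n, params, params$node_spacing)
  # A has zero end rows (not symmetric), so factor with a general solve
  lhs_inv <- solve(params$gamma * diag(n) + A)
  for (t in seq_len(params$t_max)) {
    F <- sample_flow(flow, nodes)
    if (stretch) {
      fh <- stretch_force(curve_with_nodes(curve, nodes), "head", volume,
                          sigma_h, params$stretch_eps)
      ft <- stretch_force(curve_with_nodes(curve, nodes), "tail", volume,
                          sigma_h, params$stretch_eps)
      F[1, ] <- F[1, ] + cap_norm(fh, params$stretch_cap)
      F[n, ] <- F[n, ] + cap_norm(ft, params$stretch_cap)
    }
    rhs <- params$gamma * nodes + F
    nodes <- lhs_inv %*% rhs
    nodes <- clamp_nodes(nodes, shape)
  }
  out <- curve_with_nodes(curve, resample_snake(nodes, params$node_spacing))
  out
}

curve_with_nodes <- function(curve, nodes) {
  curve$nodes <- nodes
  curve
}

cap_norm <- function(v, cap) {
  nv <- sqrt(sum(v^2))
  if (nv > cap) v * (cap / nv) else v
}

# Arclength resampling that preserves both endpoints and keeps consecutive
# node distances within [0.5, 2] * spacing.
resample_snake <- function(nodes, spacing) {
  total <- polyline_length(nodes)
  if (total < 2 * spacing) {
    # too short to resample: keep endpoints plus midpoint
    mid <- resample_polyline(nodes, max(total / 2, 1e-6))
    k <- nrow(mid)
    if (k >= 3) return(mid[c(1, ceiling(k / 2), k), , drop = FALSE])
    return(nodes)
  }
  dense <- resample_polyline(nodes, 0.25)
  seg <- sqrt(rowSums(diff(dense)^2))
  cum <- c(0, cumsum(seg))
  targets <- seq(0, total, by = spacing)
  if (total - targets[length(targets)] > 0.5 * spacing) {
    targets <- c(targets, total)
  } else {
    targets[length(targets)] <- total
  }
  idx <- vapply(targets, function(s) which.min(abs(cum - s)), integer(1))
  dense[idx, , drop = FALSE]
}

#' Initialize a snake from a seed
#'
#' The initial curve has exactly 3 nodes: the seed plus one node at
#' `extend_step` along each of the two principal (centerline) directions
#' `+/- ev1` of the local Hessian.
#'
#' @param seed one-row data frame (or list) with `x`, `y`, `z`, `label`;
#'   the seed must be unlabeled.
#' @param volume an `svf_volume`.
#' @param sigma_h Hessian scale.
#' @param extend_step initial half-length of the curve (voxels).
#' @param id positive integer curve id to assign.
#' @return A `snake_curve` with 3 nodes and both ends growing. The caller is
#'   responsible for labeling the seed with `id` in its seed list.
#' @export
init_curve <- function(seed, volume, sigma_h = 1.5, extend_step = 1.5,
                       id = 1L) {
  if (seed$label != 0L) stop("seed is already labeled (owned by a curve)")
  p <- c(seed$x, seed$y, seed$z)
  hi <- hessian_at(volume, p, sigma_h)
  ev1 <- hi$vectors[, 1]
  nodes <- rbind(p - extend_step * ev1, p, p + extend_step * ev1)
  nodes <- clamp_nodes(nodes, vol_shape(volume))
  new_snake_curve(id, nodes)
}
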