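# The full tracer: bidirectional extension with seed labeling, collision
# detection against other curves' labeled seeds, backoff at branch points,
# and the outer loop over the seed list.

#' Extend a growing snake and claim nearby seeds
#'
#' Each growing end appends one node at `extend_step` along its outward unit
#' tangent; the curve is then re-deformed in the flow field, and every
#' unlabeled seed within the claim radius of any curve node is labeled with
#' the curve's id. An end converges when its raw stretch magnitude stays
#' below `stretch_eps` for 3 consecutive extensions, when it sits in
#' background intensity (< `bg_floor`) for 3 consecutive extensions, when it
#' leaves the volume bounds, or when it stalls (net end displacement below
#' one voxel over 3 consecutive extensions -- the equilibrium between the
#' inward flow pull and the outward stretch push at a neurite terminal).
#'
#' @param curve a `snake_curve` with at least one growing end.
#' @param seeds a `seed_list` (or seed data frame).
#' @param flow a `flow_field`.
#' @param volume the `svf_volume` (stretch force, background test).
#' @param params a [snake_params()] object.
#' @param sigma_h Hessian scale.
#' @return A list with the updated `curve` and `seeds`.
#' @export
extend_and_label <- function(curve, seeds, flow, volume, params,
                             sigma_h = 1.5) {
  if (!any(curve$state == "growing")) stop("no growing end to extend")
  shape <- vol_shape(volume)
  nodes <- curve$nodes
  n <- nrow(nodes)
  grew <- c(head = FALSE, tail = FALSE)
  if (curve$state["head"] == "growing") {
    tang <- nodes[1, ] - nodes[2, ]
    nt <- sqrt(sum(tang^2))
    if (nt > 1e-9) {
      cand <- nodes[1, ] + params$extend_step * tang / nt
      if (all(cand >= 0) && all(cand <= shape - 1)) {
        nodes <- rbind(cand, nodes)
        grew["head"] <- TRUE
      } else {
        curve$state["head"] <- "converged"
      }
    } else curve$state["head"] <- "converged"
  }
  n <- nrow(nodes)
  if (curve$state["tail"] == "growing") {
    tang <- nodes[n, ] - nodes[n - 1, ]
    nt <- sqrt(sum(tang^2))
    if (nt > 1e-9) {
      cand <- nodes[n, ] + params$extend_step * tang / nt
      if (all(cand >= 0) && all(cand <= shape - 1)) {
        nodes <- rbind(nodes, cand)
        grew["tail"] <- TRUE
      } else {
        curve$state["tail"] <- "converged"
      }
    } else curve$state["tail"] <- "converged"
  }
  curve$nodes <- nodes
  curve <- deform_curve(curve, flow, volume, params, sigma_h)

  # convergence bookkeeping per grown end
  for (end in c("head", "tail")) {
    if (!grew[[end]] || curve$state[end] != "growing") next
    f <- stretch_force(curve, end, volume, sigma_h, params$stretch_eps)
    mag <- attr(f, "magnitude")
    curve$stretch_ok[end] <- if (mag < params$stretch_eps)
      curve$stretch_ok[end] + 1L else 0L
    node <- if (end == "head") curve$nodes[1, ]
            else curve$nodes[nrow(curve$nodes), ]
    inten <- cpp_sample_trilinear(volume$data, as_pts_matrix(node))
    curve$bg_count[end] <- if (inten < params$bg_floor)
      curve$bg_count[end] + 1L else 0L
    # stagnation: at a neurite terminal the flow pull and the stretch push
    # balance, so the end hovers without net displacement
    hist <- c(curve$end_hist[[end]], list(node))
    if (length(hist) > 4) hist <- hist[-1]
    curve$end_hist[[end]] <- hist
    stalled <- length(hist) == 4 &&
      sqrt(sum((hist[[4]] - hist[[1]])^2)) < 1.0
    if (curve$stretch_ok[end] >= 3L || curve$bg_count[end] >= 3L || stalled)
      curve$state[end] <- "converged"
  }

  # claim unlabeled seeds near the curve
  claim_r <- claim_radius_of(curve, params)
  free <- which(seeds$label == 0L)
  if (length(free) > 0) {
    pts <- as.matrix(seeds[free, c("x", "y", "z")])
    dmin <- cpp_nn_dist(pts, curve$nodes)
    hit <- free[dmin <= claim_r]
    if (length(hit) > 0) seeds$label[hit] <- curve$id
  }
  list(curve = curve, seeds = seeds)
}

claim_radius_of <- function(curve, params) {
  if (!is.null(params$claim_radius)) return(params$claim_radius)
  mr <- curve$mean_radius
  if (is.na(mr)) 2 else max(2, mr)
}

#' Detect a branch collision at the growing ends
#'
#' If a growing end lies within the claim radius of a seed labeled by a
#' *different* curve, that seed's position is recorded as a branching point
#' and the end's state becomes `"collided"`. Seeds labeled by the curve
#' itself are ignored.
#'
#' @param curve a `snake_curve`.
#' @param seeds a `seed_list`.
#' @param params a [snake_params()] object.
#' @param curves optional list of already-traced `snake_curve`s. When given,
#'   a foreign seed triggers a collision only if it also lies within
#'   `anchor_tol` of its owning curve's polyline; this suppresses stray
#'   cross-claimed seeds (seeds sitting on *this* curve's limb that a passing
#'   curve claimed), which would otherwise place branch points
#'   `claim_radius / sin(branch angle)` away from the true junction.
#' @param anchor_tol anchoring distance in voxels (default `node_spacing`).
#' @return A list with the updated `curve` and `events`, a data frame (one
#'   row per collision this call; zero rows when none) with columns `x`, `y`,
#'   `z`, `other`, `end`.
#' @export
detect_collision <- function(curve, seeds, params, curves = NULL,
                             anchor_tol = params$node_spacing) {
  events <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                       other = integer(), end = character())
  claim_r <- claim_radius_of(curve, params)
  foreign <- seeds$label != 0L & seeds$label != curve$id
  if (any(foreign) && !is.null(curves)) {
    ids <- vapply(curves, function(cv) cv$id, integer(1))
    fidx <- which(foreign)
    pts <- as.matrix(seeds[fidx, c("x", "y", "z")])
    for (o in unique(seeds$label[fidx])) {
      j <- which(ids == o)
      if (length(j) != 1) next   # owner was rejected; keep its seeds eligible
      sel <- seeds$label[fidx] == o
      danchor <- cpp_nn_dist(pts[sel, , drop = FALSE], curves[[j]]$nodes)
      foreign[fidx[sel][danchor > anchor_tol]] <- FALSE
    }
  }
  if (any(foreign)) {
    pts <- as.matrix(seeds[foreign, c("x", "y", "z")])
    labs <- seeds$label[foreign]
    n <- nrow(curve$nodes)
    for (end in c("head", "tail")) {
      if (curve$state[end] != "growing") next
      node <- if (end == "head") curve$nodes[1, ] else curve$nodes[n, ]
      d <- sqrt(colSums((t(pts) - node)^2))
      j <- which.min(d)
      if (d[j] <= claim_r) {
        curve$state[end] <- "collided"
        events <- rbind(events, data.frame(
          x = pts[j, 1], y = pts[j, 2], z = pts[j, 3],
          other = labs[j], end = end))
        curve$branch_hits <- rbind(curve$branch_hits, data.frame(
          x = pts[j, 1], y = pts[j, 2], z = pts[j, 3], other = labs[j]))
      }
    }
  }
  list(curve = curve, events = events)
}

#' Cut back a collided end
#'
#' Removes nodes from the given end until the removed polyline length
#' reaches `D` or only 3 nodes remain. Keeps the branch-hit registry: the
#' collision position stays recorded even though the nodes are trimmed. The
#' cut-back prevents the cross-section contours of the two curves from
#' intersecting in the branching region.
#'
#' @param curve a `snake_curve`.
#' @param end `"head"` or `"tail"`.
#' @param D cut-back length in voxels (>= 0; typically twice the curve's mean
#'   estimated radius).
#' @return The trimmed `snake_curve`.
#' @export
backoff <- function(curve, end = c("head", "tail"), D) {
  end <- match.arg(end)
  if (D < 0) stop("`D` must be >= 0")
  if (D == 0) return(curve)
  nodes <- curve$nodes
  removed <- 0
  while (nrow(nodes) > 3 && removed < D) {
    n <- nrow(nodes)
    if (end == "head") {
      removed <- removed + sqrt(sum((nodes[1, ] - nodes[2, ])^2))
      nodes <- nodes[-1, , drop = FALSE]
    } else {
      removed <- removed + sqrt(sum((nodes[n, ] - nodes[n - 1, ])^2))
      nodes <- nodes[-n, , drop = FALSE]
    }
  }
  curve$nodes <- nodes
  curve
}

#' Trace all curves from a seed list
#'
#' The outer tracing loop: repeatedly pop the highest-response unlabeled seed
#' (ties broken by lexicographic position), initialize a 3-node snake along
#' the local principal direction, alternate extension/deformation with seed
#' labeling and collision detection until both ends stop growing, cut back
#' collided ends by `D = backoff_factor * mean_radius`, and accept the curve
#' if it still has at least 3 nodes. The loop ends when every seed is
#' labeled. Deterministic for fixed inputs.
#'
#' @param volume the raw `svf_volume` (stretch force and background tests are
#'   evaluated here).
#' @param seeds a `seed_list`.
#' @param flow a `flow_field` (GVF of the SVF-enhanced volume).
#' @param params a [snake_params()] object.
#' @param sigma_h Hessian scale.
#' @param init_radius working radius estimate (voxels) before any contour
#'   fit; used for the backoff distance. Conventionally `r_min` of the
#'   filter parameters.
#' @return A `neuron_trace`: list of accepted `snake_curve`s plus a
#'   `branch_points` data frame (`x`, `y`, `z`, `parent`, `child`).
#' @export
trace_all <- function(volume, seeds, flow, params = snake_params(),
                      sigma_h = 1.5, init_radius = 5) {
  assert_volume(volume)
  seeds <- as.data.frame(seeds)
  curves <- list()
  branch_points <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                              parent = integer(), child = integer())
  next_id <- 1L
  while (any(seeds$label == 0L)) {
    free <- which(seeds$label == 0L)
    ord <- free[order(-seeds$response[free], seeds$x[free], seeds$y[free],
                      seeds$z[free])]
    s <- seeds[ord[1], ]
    curve <- init_curve(s, volume, sigma_h, params$extend_step, id = next_id)
    seeds$label[ord[1]] <- next_id
    curve$mean_radius <- init_radius
    n_ext <- 0L
    while (any(curve$state == "growing") &&
           n_ext < params$max_extensions) {
      res <- extend_and_label(curve, seeds, flow, volume, params, sigma_h)
      curve <- res$curve
      seeds <- res$seeds
      col <- detect_collision(curve, seeds, params, curves = curves)
      curve <- col$curve
      if (nrow(col$events) > 0) {
        branch_points <- rbind(branch_points, data.frame(
          x = col$events$x, y = col$events$y, z = col$events$z,
          parent = col$events$other, child = curve$id))
      }
      n_ext <- n_ext + 1L
    }
    D <- params$backoff_factor * curve$mean_radius
    for (end in c("head", "tail")) {
      if (curve$state[end] == "collided") curve <- backoff(curve, end, D)
    }
    if (nrow(curve$nodes) >= 3) curves[[length(curves) + 1L]] <- curve
    next_id <- next_id + 1L
  }
  new_neuron_trace(curves, branch_points)
}

new_neuron_trace <- function(curves, branch_points = NULL) {
  if (is.null(branch_points))
    branch_points <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                                parent = integer(), child = integer())
  ids <- vapply(curves, function(cv) cv$id, integer(1))
  if (anyDuplicated(ids)) stop("curve ids must be unique")
  structure(list(curves = curves, branch_points = branch_points),
            class = "neuron_trace")
}

#' @export
print.neuron_trace <- function(x, ...) {
  cat(sprintf("<neuron_trace> %d curve(s), total length %.1f voxels, %d branch point(s)\n",
              length(x$curves), skeleton_length(x),
              nrow(x$branch_points)))
  invisible(x)
}

# All curves of a trace as a list of node matrices.
trace_polylines <- function(trace) {
  lapply(trace$curves, function(cv) cv$nodes)
}
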