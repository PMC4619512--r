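# Cross-section radius estimation with the 2-D sliding band filter: at each
# snake node, n rays radiate in the plane orthogonal to the local tangent and
# each ray's band slides over (r_min, r_max) to the position of maximal mean
# convergence toward the node, giving n boundary points of the (generally
# non-circular) neurite cross-section.

#' Local orthonormal frame at a snake node
#'
#' `v1` is the central-difference unit tangent (one-sided at the ends);
#' `v2` is the global axis least aligned with `v1`, projected onto the
#' orthogonal plane and normalized; `v3 = v1 x v2`. The frame is
#' right-handed (`v1 = v2 x v3`).
#'
#' @param curve a `snake_curve` (or any list with an `nodes` matrix) with at
#'   least 3 nodes.
#' @param node_index node position, 1-based.
#' @return A `local_frame` with unit fields `v1`, `v2`, `v3`.
#' @export
local_frame <- function(curve, node_index) {
  nodes <- if (is.matrix(curve)) curve else curve$nodes
  n <- nrow(nodes)
  if (n < 3) stop("curve must have at least 3 nodes")
  i <- as.integer(node_index)
  if (i < 1 || i > n) stop("`node_index` out of range")
  tang <- if (i == 1) nodes[2, ] - nodes[1, ]
          else if (i == n) nodes[n, ] - nodes[n - 1, ]
          else nodes[i + 1, ] - nodes[i - 1, ]
  nt <- sqrt(sum(tang^2))
  if (nt < 1e-12) stop("zero tangent at the requested node")
  v1 <- tang / nt
  ax <- diag(3)[, which.min(abs(v1))]
  v2 <- ax - sum(ax * v1) * v1
  v2 <- v2 / sqrt(sum(v2^2))
  v3 <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  structure(list(v1 = v1, v2 = v2, v3 = v3), class = "local_frame")
}

#' Sliding-band boundary of one cross-section
#'
#' For each of `n` in-plane directions `u_k = cos(theta_k) v2 +
#' sin(theta_k) v3` (`theta_k = 2 pi k / n`), the boundary radius `r_k` is
#' the integer band center in the strict range `(r_min, r_max)` maximizing
#' the band-averaged convergence index toward the center; ties break toward
#' the smaller radius. On a flat (zero-gradient) volume every response is 0,
#' so the tie rule yields the degenerate output `r_k = r_min + 1`.
#'
#' @param grad a `gradient_field` of the raw volume.
#' @param center cross-section center (length 3, inside the volume).
#' @param frame a [local_frame()].
#' @param n number of boundary rays (>= 4; 16 is sufficient in practice).
#' @param params an [filter_params()] object (uses `r_min`, `r_max`, `d`).
#' @return An `sbf_contour`: `center`, `frame`, `boundary` (`n x 3`),
#'   `radii`, `responses`, `mean_radius`.
#' @export
sbf_boundary <- function(grad, center, frame, n = 16, params) {
  assert_gradient(grad)
  stopifnot(inherits(frame, "local_frame"),
            inherits(params, "svf_filter_params"))
  if (n < 4) stop("`n` must be >= 4")
  center <- as.numeric(center)
  shape <- dim(grad$gx)
  if (any(center < 0) || any(center > shape - 1))
    stop("contour center is outside the volume bounds")
  rays <- cpp_sbf_rays(grad$gx, grad$gy, grad$gz, center, frame$v2, frame$v3,
                       as.integer(n), params$r_min, params$r_max, params$d)
  theta <- 2 * pi * (seq_len(n) - 1) / n
  dirs <- outer(cos(theta), frame$v2) + outer(sin(theta), frame$v3)
  boundary <- matrix(center, n, 3, byrow = TRUE) + rays[, 1] * dirs
  structure(list(center = center, frame = frame, boundary = boundary,
                 radii = rays[, 1], responses = rays[, 2],
                 mean_radius = mean(rays[, 1])),
            class = "sbf_contour")
}

#' @export
print.sbf_contour <- function(x, ...) {
  cat(sprintf("<sbf_contour> %d boundary points, radii [%.1f, %.1f], mean %.2f\n",
              length(x$radii), min(x$radii), max(x$radii), x$mean_radius))
  invisible(x)
}

#' Cross-section contours along a whole trace
#'
#' One contour per snake node, except nodes within `backoff_D` polyline
#' (arclength) distance of a branch point, where radius estimation is skipped
#' (the surface step interpolates across the gap). Each curve's
#' `mean_radius` is updated to the mean over its contours.
#'
#' @param trace a `neuron_trace`.
#' @param grad a `gradient_field` of the raw volume.
#' @param n boundary points per contour.
#' @param params an [filter_params()] object.
#' @param backoff_D exclusion distance around branch points (voxels).
#' @return A list with `contours` (each carrying `curve_id` and
#'   `node_index`) and the updated `trace`.
#' @export
contours_for_trace <- function(trace, grad, n = 16, params,
                               backoff_D = 2 * params$r_min) {
  stopifnot(inherits(trace, "neuron_trace"))
  bp <- trace$branch_points
  contours <- list()
  for (ci in seq_along(trace$curves)) {
    cv <- trace$curves[[ci]]
    nodes <- cv$nodes
    m <- nrow(nodes)
    arc <- c(0, cumsum(sqrt(rowSums(diff(nodes)^2))))
    skip <- rep(FALSE, m)
    if (nrow(bp) > 0 && backoff_D > 0) {
      for (b in seq_len(nrow(bp))) {
        p <- c(bp$x[b], bp$y[b], bp$z[b])
        d <- sqrt(colSums((t(nodes) - p)^2))
        j <- which.min(d)
        if (d[j] <= backoff_D)
          skip <- skip | abs(arc - arc[j]) < backoff_D
      }
    }
    radii <- numeric(0)
    for (i in seq_len(m)) {
      if (skip[i]) next
      fr <- local_frame(cv, i)
      ct <- sbf_boundary(grad, nodes[i, ], fr, n, params)
      ct$curve_id <- cv$id
      ct$node_index <- i
      contours[[length(contours) + 1L]] <- ct
      radii <- c(radii, ct$mean_radius)
    }
    if (length(radii) > 0)
      trace$curves[[ci]]$mean_radius <- mean(radii)
  }
  list(contours = contours, trace = trace)
}
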