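# SWC morphology export and a simple contour-lofted OBJ mesh.

#' Assemble a trace into an SWC node table
#'
#' Each curve becomes a chain of SWC nodes. A curve with a branch hit is
#' parented at the nearest node of the other (earlier) curve, with its
#' collided end attached first; curves without hits become roots. Node ids
#' are contiguous from 1 and every parent precedes its children. Type code 0
#' marks regular nodes and 5 marks branch (fork) nodes. Node radii come from
#' the owning curve's `mean_radius` (1 when never estimated); branch nodes
#' keep the radius of the parent curve's nearest estimated node.
#'
#' @param trace a `neuron_trace`.
#' @param radii optional named list mapping curve id -> per-node radius
#'   vector (e.g. from contour fitting); falls back to the curve mean.
#' @return A data frame with SWC columns `id`, `type`, `x`, `y`, `z`,
#'   `radius`, `parent`.
#' @export
build_tree <- function(trace, radii = NULL) {
  stopifnot(inherits(trace, "neuron_trace"))
  nodes_df <- data.frame(id = integer(), type = integer(), x = numeric(),
                         y = numeric(), z = numeric(), radius = numeric(),
                         parent = integer())
  if (length(trace$curves) == 0) return(nodes_df)
  ids <- vapply(trace$curves, function(cv) cv$id, integer(1))
  curve_rows <- list()   # per curve: SWC ids of its nodes, in node order
  next_id <- 1L
  for (ci in order(ids)) {
    cv <- trace$curves[[ci]]
    nd <- cv$nodes
    m <- nrow(nd)
    r <- if (!is.null(radii) && !is.null(radii[[as.character(cv$id)]])) {
      rep_len(radii[[as.character(cv$id)]], m)
    } else rep(if (is.na(cv$mean_radius)) 1 else cv$mean_radius, m)

    attach_id <- -1L
    ord <- seq_len(m)
    if (nrow(cv$branch_hits) > 0) {
      hit <- cv$branch_hits[1, ]
      parent_curve <- as.character(hit$other)
      prows <- curve_rows[[parent_curve]]
      if (!is.null(prows)) {
        pcv <- trace$curves[[which(ids == hit$other)]]
        d <- sqrt(colSums((t(pcv$nodes) - c(hit$x, hit$y, hit$z))^2))
        j <- which.min(d)
        attach_id <- prows[j]
        nodes_df$type[nodes_df$id == attach_id] <- 5L
        # attach the collided end first so the chain hangs off the parent
        dhead <- sum((nd[1, ] - c(hit$x, hit$y, hit$z))^2)
        dtail <- sum((nd[m, ] - c(hit$x, hit$y, hit$z))^2)
        if (dtail < dhead) ord <- rev(ord)
      }
    }
    sw_ids <- next_id:(next_id + m - 1L)
    parents <- c(attach_id, sw_ids[-m])
    nodes_df <- rbind(nodes_df, data.frame(
      id = sw_ids, type = 0L,
      x = nd[ord, 1], y = nd[ord, 2], z = nd[ord, 3],
      radius = r[ord], parent = parents))
    row_ids <- integer(m)
    row_ids[ord] <- sw_ids    # map node order -> SWC id
    curve_rows[[as.character(cv$id)]] <- row_ids
    next_id <- next_id + m
  }
  rownames(nodes_df) <- NULL
  nodes_df
}

#' Write an SWC morphology file
#'
#' Standard whitespace-delimited 7-column SWC
#' (`id type x y z radius parent`), with coordinates and radii scaled by the
#' voxel spacing (radii use the mean spacing).
#'
#' @param nodes SWC node data frame (see `build_tree()`).
#' @param path output file.
#' @param spacing per-axis voxel spacing applied on export.
#' @param comment extra header comment lines (without the leading `#`).
#' @return `path`, invisibly.
#' @export
write_swc <- function(nodes, path, spacing = c(1, 1, 1), comment = NULL) {
  lines <- c("# SWC morphology written by svftrace",
             sprintf("# voxel spacing %g %g %g", spacing[1], spacing[2],
                     spacing[3]),
             if (!is.null(comment)) paste("#", comment))
  if (nrow(nodes) > 0) {
    body <- sprintf("%d %d %.6g %.6g %.6g %.6g %d",
                    nodes$id, nodes$type,
                    nodes$x * spacing[1], nodes$y * spacing[2],
                    nodes$z * spacing[3],
                    nodes$radius * mean(spacing), nodes$parent)
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an SWC morphology file
#'
#' @param path SWC file.
#' @return A data frame with columns `id`, `type`, `x`, `y`, `z`, `radius`,
#'   `parent`.
#' @export
read_swc <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0)
    return(data.frame(id = integer(), type = integer(), x = numeric(),
                      y = numeric(), z = numeric(), radius = numeric(),
                      parent = integer()))
  fields <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  if (ncol(fields) != 7) stop("malformed SWC: expected 7 columns")
  data.frame(id = as.integer(fields[, 1]), type = as.integer(fields[, 2]),
             x = fields[, 3], y = fields[, 4], z = fields[, 5],
             radius = fields[, 6], parent = as.integer(fields[, 7]))
}

#' Loft cross-section contours into an OBJ triangle mesh
#'
#' Adjacent contours along each curve (equal point count `n`) are joined by a
#' quad strip split into `2n` triangles; the two open ends of each curve are
#' closed with fans around the contour centers. Each interior (side) edge is
#' shared by exactly two triangles, so every per-curve tube is manifold;
#' branch junctions are left open. This is deliberately simple plumbing so
#' the pipeline yields a renderable surface.
#'
#' @param contours list of `sbf_contour`s carrying `curve_id` and
#'   `node_index` (from [contours_for_trace()]).
#' @param path output OBJ file, or `NULL` to skip writing.
#' @return Invisibly, a list with `vertices` (matrix) and `faces` (matrix of
#'   1-based vertex indices).
#' @export
loft_mesh <- function(contours, path = NULL) {
  if (length(contours) == 0) stop("no contours to loft")
  ns <- vapply(contours, function(ct) length(ct$radii), integer(1))
  if (length(unique(ns)) != 1)
    stop("all contours must have the same number of boundary points")
  n <- ns[1]
  ids <- vapply(contours, function(ct) ct$curve_id %||% 1L, numeric(1))
  verts <- matrix(numeric(0), ncol = 3)
  faces <- matrix(integer(0), ncol = 3)
  for (cid in unique(ids)) {
    sel <- which(ids == cid)
    sel <- sel[order(vapply(contours[sel],
                            function(ct) ct$node_index %||% 0L, numeric(1)))]
    if (length(sel) < 2)
      stop("need at least 2 contours per curve to loft")
    base <- nrow(verts)
    for (k in sel) verts <- rbind(verts, contours[[k]]$boundary)
    m <- length(sel)
    for (s in seq_len(m - 1)) {
      a0 <- base + (s - 1) * n
      b0 <- base + s * n
      for (k in seq_len(n)) {
        k2 <- if (k == n) 1L else k + 1L
        # wound so the side normals point outward (theta runs CCW about v1)
        faces <- rbind(faces,
                       c(a0 + k, b0 + k2, b0 + k),
                       c(a0 + k, a0 + k2, b0 + k2))
      }
    }
    # end caps: fan around the first/last contour centers
    c1 <- contours[[sel[1]]]$center
    c2 <- contours[[sel[m]]]$center
    verts <- rbind(verts, c1, c2)
    i1 <- nrow(verts) - 1L
    i2 <- nrow(verts)
    for (k in seq_len(n)) {
      k2 <- if (k == n) 1L else k + 1L
      faces <- rbind(faces, c(i1, base + k2, base + k))
      last0 <- base + (m - 1) * n
      faces <- rbind(faces, c(i2, last0 + k, last0 + k2))
    }
  }
  if (!is.null(path)) {
    lines <- c("# OBJ mesh written by svftrace",
               sprintf("v %.6g %.6g %.6g", verts[, 1], verts[, 2], verts[, 3]),
               sprintf("f %d %d %d", faces[, 1], faces[, 2], faces[, 3]))
    writeLines(lines, path)
  }
  invisible(list(vertices = verts, faces = faces))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
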