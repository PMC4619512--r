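# Evaluation metrics against ground-truth centerlines: mean point deviation,
# length-based precision/recall, and skeleton length.

# Accept a trace, a list of polylines, or a single point matrix.
as_polyline_list <- function(x) {
  if (inherits(x, "neuron_trace")) return(trace_polylines(x))
  if (is.matrix(x)) return(list(x))
  if (is.data.frame(x)) return(list(as.matrix(x[, c("x", "y", "z")])))
  if (is.list(x)) return(lapply(x, as_pts_matrix))
  stop("cannot interpret input as polyline(s)")
}

as_point_matrix <- function(x) {
  if (inherits(x, "neuron_trace")) return(do.call(rbind, trace_polylines(x)))
  if (is.matrix(x)) return(as_pts_matrix(x))
  if (is.data.frame(x)) {
    if (all(c("x", "y", "z") %in% names(x)))
      return(as.matrix(x[, c("x", "y", "z")]))
    return(as.matrix(x))
  }
  if (is.list(x)) return(do.call(rbind, lapply(x, as_pts_matrix)))
  stop("cannot interpret input as a point set")
}

#' Mean point deviation from a gold standard
#'
#' `D(P_s, P_g) = (1/N) * sum over p in P_s of the Euclidean distance from p
#' to its nearest point in P_g`. Nearest neighbours are found with a
#' uniform-grid spatial index (exact distances).
#'
#' @param P_s evaluated point set (seeds, trace nodes, ...): a matrix, data
#'   frame with `x`, `y`, `z`, trace, or list of polylines.
#' @param P_g gold-standard point set (typically a densely resampled
#'   centerline).
#' @return The mean nearest-neighbour distance (voxels).
#' @export
point_deviation <- function(P_s, P_g) {
  ps <- as_point_matrix(P_s)
  pg <- as_point_matrix(P_g)
  if (nrow(ps) == 0) stop("evaluated point set is empty")
  if (nrow(pg) == 0) stop("gold-standard point set is empty")
  mean(cpp_nn_dist(ps, pg))
}

#' Length-based precision and recall of a trace
#'
#' Both the automated trace and the gold standard are resampled at
#' `step`-voxel arc steps. An automated sample is *correct* when it lies
#' within `match_tol` of some gold sample; precision is the correct fraction
#' of the automated length. Recall is computed symmetrically from the gold
#' side: the fraction of gold samples covered within `match_tol` by the
#' automated trace (this avoids rewarding oversampled automated traces).
#'
#' @param auto automated trace: a `neuron_trace`, matrix, or list of
#'   polylines.
#' @param gold gold-standard centerline(s): matrix or list of polylines.
#' @param match_tol matching tolerance in voxels (> 0; default 2).
#' @param step resampling step (voxels).
#' @return A `trace_match` list: `precision`, `recall`, `correct_length`,
#'   `total_auto_length`, `gold_length`, `match_tol`.
#' @export
precision_recall <- function(auto, gold, match_tol = 2, step = 0.5) {
  if (match_tol <= 0) stop("`match_tol` must be > 0")
  auto_pl <- as_polyline_list(auto)
  gold_pl <- as_polyline_list(gold)
  if (length(gold_pl) == 0 || sum(vapply(gold_pl, nrow, integer(1))) == 0)
    stop("empty gold standard")
  gold_s <- do.call(rbind, lapply(gold_pl, resample_polyline, step = step))
  auto_s <- if (length(auto_pl) > 0)
    do.call(rbind, lapply(auto_pl, resample_polyline, step = step))
  else matrix(numeric(0), ncol = 3)

  total_auto <- nrow(auto_s) * step
  gold_len <- nrow(gold_s) * step
  if (nrow(auto_s) == 0) {
    correct <- 0
    covered <- 0
  } else {
    correct <- sum(cpp_nn_dist(auto_s, gold_s) <= match_tol) * step
    covered <- sum(cpp_nn_dist(gold_s, auto_s) <= match_tol) * step
  }
  structure(list(
    precision = if (total_auto > 0) correct / total_auto else NA_real_,
    recall = covered / gold_len,
    correct_length = correct,
    total_auto_length = total_auto,
    gold_length = gold_len,
    match_tol = match_tol), class = "trace_match")
}

#' @export
print.trace_match <- function(x, ...) {
  cat(sprintf("<trace_match> precision %.3f, recall %.3f (tol %g voxels; auto %.1f / gold %.1f voxels)\n",
              x$precision, x$recall, x$match_tol, x$total_auto_length,
              x$gold_length))
  invisible(x)
}

#' Total skeleton length of a trace
#'
#' Sum of the polyline arclengths over all curves, in voxels.
#'
#' @param trace a `neuron_trace` (or list of polylines).
#' @return A scalar length.
#' @export
skeleton_length <- function(trace) {
  pl <- if (inherits(trace, "neuron_trace")) trace_polylines(trace)
        else as_polyline_list(trace)
  if (length(pl) == 0) return(0)
  sum(vapply(pl, polyline_length, numeric(1)))
}
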