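#' Add false edges to a graph
#'
#' Inserts the requested number of edges between uniformly random,
#' previously non-adjacent node pairs — the structural signature of barcode
#' collisions and chimeric products, which join nodes that are distant in
#' physical space. On bipartite graphs the new edges respect bipartiteness
#' by default (collision artifacts still join opposite parts). An optional
#' minimum Euclidean length makes every false edge a genuine long-range
#' shortcut.
#'
#' @param g a [spatial_graph].
#' @param ratio_or_count false edges to add: a count if >= 1, otherwise a
#'   fraction of the current edge count.
#' @param min_length optional minimum ground-truth Euclidean length of the
#'   added edges (requires positions).
#' @param respect_parts on bipartite graphs, draw false edges across parts
#'   (default `TRUE`).
#' @param seed integer seed.
#' @return List with `graph` (the perturbed [spatial_graph]) and `record`
#'   (a `"perturbation_record"`: `added_edges`, `removed_edges`,
#'   `false_ratio`, `missing_ratio`, `original_edges`).
#' @export
add_false_edges <- function(g, ratio_or_count, min_length = NULL,
                            respect_parts = TRUE, seed = 1L) {
  m <- nrow(g$edges)
  n_add <- if (ratio_or_count < 1) round(ratio_or_count * m) else as.integer(ratio_or_count)
  if (n_add < 0) stop("'ratio_or_count' must be nonnegative")
  set.seed(seed)
  have <- edge_key(g$edges, g$n)
  added <- matrix(integer(), ncol = 2L)
  tries <- 0L; max_tries <- 200L * max(n_add, 1L) + 1000L
  while (nrow(added) < n_add) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop(sprintf("could not place %d false edges (placed %d): too few eligible non-adjacent pairs",
                   n_add, nrow(added)))
    }
    u <- sample.int(g$n, 1L); v <- sample.int(g$n, 1L)
    if (u == v) next
    if (!is.null(g$parts) && respect_parts && g$parts[u] == g$parts[v]) next
    pair <- if (u < v) c(u, v) else c(v, u)
    k <- (pair[1L] - 1) * as.double(g$n) + pair[2L]
    if (k %in% have) next
    if (!is.null(min_length)) {
      if (is.null(g$positions)) stop("'min_length' requires positions")
      len <- sqrt(sum((g$positions[u, ] - g$positions[v, ])^2))
      if (len < min_length) next
    }
    added <- rbind(added, pair)
    have <- c(have, k)
  }
  new_weights <- if (!is.null(g$weights)) {
    # a false edge is still an observed interaction; give it the minimum
    # observed count so weight-based ranking can demote it
    c(g$weights, rep(min(g$weights), nrow(added)))
  }
  out <- spatial_graph(rbind(g$edges, added), n = g$n, weights = new_weights,
                       positions = g$positions, parts = g$parts, ids = g$ids)
  record <- structure(
    list(added_edges = added, removed_edges = matrix(integer(), ncol = 2L),
         false_ratio = if (m > 0) nrow(added) / m else NA_real_,
         missing_ratio = 0, original_edges = m, n = g$n),
    class = "perturbation_record"
  )
  list(graph = out, record = record)
}

#' Remove edges while preserving connectivity
#'
#' Deletes the requested fraction of edges by rejection sampling: a random
#' edge is removed and the deletion is reverted if it disconnects the
#' graph. Models sparse interaction capture (shallow sequencing).
#'
#' @param g a connected [spatial_graph].
#' @param missing_ratio fraction of the original edge count to remove, in
#'   `[0, 1)`.
#' @param seed integer seed.
#' @param max_attempts attempt budget before giving up (default
#'   `100 * |E|`).
#' @return List with `graph` and `record` as in [add_false_edges()].
#' @export
remove_edges <- function(g, missing_ratio, seed = 1L, max_attempts = NULL) {
  if (missing_ratio < 0 || missing_ratio >= 1) {
    stop("'missing_ratio' must lie in [0, 1)")
  }
  m <- nrow(g$edges)
  n_remove <- round(missing_ratio * m)
  if (is.null(max_attempts)) max_attempts <- 100L * m
  ig <- sg_igraph(g)
  if (igraph::components(ig)$no != 1L) stop("graph must be connected")
  set.seed(seed)
  removed_idx <- integer()
  attempts <- 0L
  alive <- rep(TRUE, m)
  while (length(removed_idx) < n_remove) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop(sprintf(
        "could not remove %d edges without disconnecting (achieved ratio %.3f)",
        n_remove, length(removed_idx) / m))
    }
    cand <- sample(which(alive), 1L)
    eid <- igraph::get_edge_ids(ig, g$edges[cand, ])
    ig2 <- igraph::delete_edges(ig, eid)
    if (igraph::components(ig2)$no == 1L) {
      ig <- ig2
      alive[cand] <- FALSE
      removed_idx <- c(removed_idx, cand)
    }
  }
  keep <- which(alive)
  out <- spatial_graph(g$edges[keep, , drop = FALSE], n = g$n,
                       weights = g$weights[keep],
                       lengths = g$lengths[keep],
                       positions = g$positions, parts = g$parts, ids = g$ids)
  record <- structure(
    list(added_edges = matrix(integer(), ncol = 2L),
         removed_edges = g$edges[removed_idx, , drop = FALSE],
         false_ratio = 0,
         missing_ratio = length(removed_idx) / m,
         original_edges = m, n = g$n),
    class = "perturbation_record"
  )
  list(graph = out, record = record)
}

#' @export
print.perturbation_record <- function(x, ...) {
  cat(sprintf("Perturbation record: %d original edges, +%d false (ratio %.3f), -%d missing (ratio %.3f)\n",
              x$original_edges, nrow(x$added_edges), x$false_ratio,
              nrow(x$removed_edges), x$missing_ratio))
  invisible(x)
}

#' Precision/recall/F1 of false-edge filtering
#'
#' Scores a filter against the ground-truth labels of a
#' [add_false_edges()] record: the positive class is "false edge", a true
#' positive is a known-false edge that the filter removed.
#'
#' @param record a `"perturbation_record"` with labelled false edges.
#' @param removed_by_filter two-column matrix of edges the filter removed.
#' @return Named numeric vector `precision`, `recall`, `f1` (0 when
#'   undefined).
#' @export
evaluate_filter <- function(record, removed_by_filter) {
  removed_by_filter <- as.matrix(removed_by_filter)
  if (length(removed_by_filter) == 0L) {
    removed_by_filter <- matrix(integer(), ncol = 2L)
  }
  if (nrow(removed_by_filter) && max(removed_by_filter) > record$n) {
    stop("filter removed edges outside the graph")
  }
  n <- record$n
  false_keys <- edge_key(record$added_edges, n)
  rem_keys <- edge_key(removed_by_filter, n)
  tp <- sum(rem_keys %in% false_keys)
  fp <- length(rem_keys) - tp
  fn <- length(false_keys) - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall, f1 = f1)
}

#' Write a perturbation record as a JSON side-car
#'
#' Keeps ground-truth noise labels next to, but out of, the main edge-list
#' file.
#'
#' @param record a `"perturbation_record"`.
#' @param path output JSON path.
#' @param ids optional external node identifiers for label translation.
#' @return `path`, invisibly.
#' @export
write_perturbation_record <- function(record, path, ids = NULL) {
  lab <- function(e) {
    dimnames(e) <- NULL
    if (!is.null(ids)) e <- matrix(ids[e], ncol = 2L)
    e
  }
  jsonlite::write_json(
    list(schema = "spatialcoherence/perturbation-record", version = 1L,
         original_edges = record$original_edges, n = record$n,
         false_ratio = record$false_ratio, missing_ratio = record$missing_ratio,
         added_edges = lab(record$added_edges),
         removed_edges = lab(record$removed_edges)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

edge_key <- function(edges, n) {
  if (!nrow(edges)) return(double())
  a <- pmin(edges[, 1L], edges[, 2L])
  b <- pmax(edges[, 1L], edges[, 2L])
  (a - 1) * as.double(n) + b
}
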