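#' Construct a spatial graph
#'
#' The central container of the package: an undirected simple graph whose
#' nodes are meant to represent points of physical space (polonies, DNA
#' pixels, molecular barcodes, ...) and whose edges record proximity events.
#' Optionally carries per-edge interaction weights (e.g. read counts),
#' per-edge metric lengths (for weighted shortest paths), bipartite part
#' labels and ground-truth node coordinates.
#'
#' Edges are canonicalised so that the smaller node index comes first and the
#' edge list is sorted; duplicate undirected pairs and self-loops are
#' rejected (use [read_graph()] to collapse duplicates found in files).
#'
#' @param edges two-column matrix (or data frame) of node indices in
#'   `1..n`, one row per undirected edge.
#' @param n number of nodes; defaults to the largest index in `edges`.
#' @param weights optional positive numeric vector, one interaction weight
#'   per edge row.
#' @param lengths optional positive numeric vector of per-edge metric
#'   lengths used by weighted shortest paths (normally produced by
#'   [weight_to_distance()]).
#' @param positions optional numeric matrix of ground-truth coordinates,
#'   `n` rows and 2 or 3 columns.
#' @param parts optional bipartite part labels, a vector of `"A"`/`"B"` of
#'   length `n`; every edge must join different parts.
#' @param ids optional character vector of external node identifiers,
#'   preserved by [write_graph()].
#'
#' @return An object of class `"spatial_graph"` with elements `n`, `edges`,
#'   `weights`, `lengths`, `positions`, `parts`, `ids`.
#' @examples
#' g <- spatial_graph(rbind(c(1, 2), c(2, 3), c(3, 1)))
#' g
#' @export
spatial_graph <- function(edges, n = NULL, weights = NULL, lengths = NULL,
                          positions = NULL, parts = NULL, ids = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(integer(), ncol = 2L)
  }
  if (ncol(edges) != 2L) stop("'edges' must have two columns")
  storage.mode(edges) <- "integer"
  dimnames(edges) <- NULL
  if (anyNA(edges)) stop("'edges' contains missing values")
  if (is.null(n)) n <- if (nrow(edges)) max(edges) else 0L
  n <- as.integer(n)
  if (n < 1L) stop("graph must have at least one node")
  if (nrow(edges) && (min(edges) < 1L || max(edges) > n)) {
    stop("edge endpoints must lie in 1..n")
  }
  if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")

  # canonical order: smaller endpoint first, rows sorted, attributes follow
  flip <- edges[, 1L] > edges[, 2L]
  if (any(flip)) edges[flip, ] <- edges[flip, 2:1]
  ord <- order(edges[, 1L], edges[, 2L])
  edges <- edges[ord, , drop = FALSE]
  key <- (edges[, 1L] - 1) * as.double(n) + edges[, 2L]
  if (anyDuplicated(key)) stop("duplicate undirected edges are not allowed")

  if (!is.null(weights)) {
    weights <- as.double(weights)[ord]
    if (length(weights) != nrow(edges)) stop("one weight per edge required")
    if (any(!is.finite(weights)) || any(weights <= 0)) {
      stop("all edge weights must be positive and finite")
    }
  }
  if (!is.null(lengths)) {
    lengths <- as.double(lengths)[ord]
    if (length(lengths) != nrow(edges)) stop("one length per edge required")
    if (any(!is.finite(lengths)) || any(lengths < 0)) {
      stop("edge lengths must be nonnegative and finite")
    }
  }
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    storage.mode(positions) <- "double"
    if (nrow(positions) != n) stop("'positions' must have one row per node")
  }
  if (!is.null(parts)) {
    parts <- as.character(parts)
    if (length(parts) != n) stop("'parts' must have one label per node")
    if (!all(parts %in% c("A", "B"))) stop("part labels must be 'A' or 'B'")
    if (nrow(edges) && any(parts[edges[, 1L]] == parts[edges[, 2L]])) {
      stop("bipartite graph has an intra-part edge")
    }
  }
  if (!is.null(ids)) {
    ids <- as.character(ids)
    if (length(ids) != n) stop("'ids' must have one identifier per node")
    if (anyDuplicated(ids)) stop("node identifiers must be unique")
  }

  structure(
    list(n = n, edges = edges, weights = weights, lengths = lengths,
         positions = positions, parts = parts, ids = ids),
    class = "spatial_graph"
  )
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat(sprintf("Spatial graph: %d nodes, %d edges, mean degree %.2f\n",
              x$n, nrow(x$edges), mean_degree(x)))
  feat <- c(
    if (!is.null(x$weights)) "weights",
    if (!is.null(x$lengths)) "edge lengths",
    if (!is.null(x$parts)) "bipartite labels",
    if (!is.null(x$positions)) sprintf("%dD positions", ncol(x$positions))
  )
  if (length(feat)) cat("  with:", paste(feat, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.spatial_graph <- function(object, ...) {
  deg <- node_degrees(object)
  comps <- igraph::components(sg_igraph(object))
  out <- list(
    n = object$n, m = nrow(object$edges), mean_degree = mean(deg),
    degree_range = range(deg), components = comps$no,
    largest_component = max(comps$csize),
    weighted = !is.null(object$weights), bipartite = !is.null(object$parts),
    has_positions = !is.null(object$positions)
  )
  class(out) <- "summary.spatial_graph"
  out
}

#' @export
print.summary.spatial_graph <- function(x, ...) {
  cat(sprintf("Spatial graph: %d nodes, %d edges\n", x$n, x$m))
  cat(sprintf("  mean degree %.2f (range %d-%d)\n",
              x$mean_degree, x$degree_range[1], x$degree_range[2]))
  cat(sprintf("  components: %d (largest: %d nodes)\n",
              x$components, x$largest_component))
  cat(sprintf("  weighted: %s; bipartite: %s; ground-truth positions: %s\n",
              x$weighted, x$bipartite, x$has_positions))
  invisible(x)
}

#' @export
plot.spatial_graph <- function(x, ...) {
  if (is.null(x$positions)) {
    stop("plotting requires ground-truth positions; see reconstruct_classical_mds()")
  }
  p <- x$positions
  graphics::plot(p[, 1], p[, 2], pch = 16, cex = 0.4, asp = 1,
                 xlab = "x", ylab = "y", ...)
  if (nrow(x$edges)) {
    graphics::segments(p[x$edges[, 1], 1], p[x$edges[, 1], 2],
                       p[x$edges[, 2], 1], p[x$edges[, 2], 2],
                       col = grDevices::adjustcolor("steelblue", 0.3))
  }
  invisible(x)
}

# igraph view of a spatial graph (hop metric unless lengths are attached and
# asked for); vertices keep their spatial_graph index.
sg_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = g$n, directed = FALSE)
  if (nrow(g$edges)) ig <- igraph::add_edges(ig, as.vector(t(g$edges)))
  ig
}

node_degrees <- function(g) {
  tabulate(g$edges, nbins = g$n)
}

#' Mean node degree
#'
#' @param g a [spatial_graph].
#' @return Average degree \eqn{\langle k \rangle = 2|E|/N}.
#' @export
mean_degree <- function(g) {
  2 * nrow(g$edges) / g$n
}

#' Number of connected components
#' @param g a [spatial_graph].
#' @return Integer component count.
#' @export
n_components <- function(g) {
  igraph::components(sg_igraph(g))$no
}

# Induced subgraph on a node subset, relabelled 1..length(nodes) following
# the order given; attaches the original indices as attribute "mapping".
sg_induced <- function(g, nodes) {
  nodes <- as.integer(nodes)
  keep <- logical(g$n)
  keep[nodes] <- TRUE
  sel <- keep[g$edges[, 1L]] & keep[g$edges[, 2L]]
  relabel <- integer(g$n)
  relabel[nodes] <- seq_along(nodes)
  sub <- spatial_graph(
    edges = matrix(relabel[g$edges[sel, , drop = FALSE]], ncol = 2L),
    n = length(nodes),
    weights = if (!is.null(g$weights)) g$weights[sel],
    lengths = if (!is.null(g$lengths)) g$lengths[sel],
    positions = if (!is.null(g$positions)) g$positions[nodes, , drop = FALSE],
    parts = if (!is.null(g$parts)) g$parts[nodes],
    ids = if (!is.null(g$ids)) g$ids[nodes]
  )
  attr(sub, "mapping") <- nodes
  sub
}

#' Restrict a graph to its largest connected component
#'
#' Experimental edge lists routinely contain small satellite components;
#' every metric in the package operates on the largest component, with a
#' warning, unless `strict = TRUE`.
#'
#' @param g a [spatial_graph].
#' @param strict if `TRUE`, a disconnected input is an error instead.
#' @param quiet suppress the warning.
#' @return A connected [spatial_graph] (the input itself when connected),
#'   with attribute `"mapping"` giving original node indices if restricted.
#' @export
largest_component <- function(g, strict = FALSE, quiet = FALSE) {
  comps <- igraph::components(sg_igraph(g))
  if (comps$no == 1L) return(g)
  if (strict) {
    stop(sprintf("graph is disconnected: %d components (sizes %s)",
                 comps$no,
                 paste(sort(comps$csize, decreasing = TRUE), collapse = ", ")))
  }
  if (!quiet) {
    warning(sprintf(
      "graph has %d components; using the largest (%d of %d nodes)",
      comps$no, max(comps$csize), g$n))
  }
  keep <- which(comps$membership == which.max(comps$csize))
  sg_induced(g, keep)
}
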