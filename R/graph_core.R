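#' All-pairs shortest-path distance matrix
#'
#' Computes the shortest-path distance matrix (SPDM), the network substitute
#' for the Euclidean distance matrix. In `"hop"` mode every edge has unit
#' length (BFS distances); in `"weighted"` mode per-edge metric lengths are
#' used (Dijkstra), which requires lengths to be attached first, normally by
#' [weight_to_distance()].
#'
#' @param g a connected [spatial_graph].
#' @param mode `"hop"` (default) or `"weighted"`.
#' @return An `N x N` symmetric numeric matrix with zero diagonal, of class
#'   `"spdm"` with attribute `metric_kind`.
#' @examples
#' g <- spatial_graph(rbind(c(1, 2), c(2, 3)))
#' shortest_path_matrix(g)[1, 3]  # two hops
#' @export
shortest_path_matrix <- function(g, mode = c("hop", "weighted")) {
  mode <- match.arg(mode)
  comps <- igraph::components(sg_igraph(g))
  if (comps$no != 1L) {
    stop(sprintf("graph is disconnected (%d components); restrict to one component first",
                 comps$no))
  }
  if (mode == "weighted" && is.null(g$lengths)) {
    stop("weighted mode requires per-edge lengths; see weight_to_distance()")
  }
  w <- if (mode == "hop") NA else g$lengths
  d <- igraph::distances(sg_igraph(g), weights = w)
  dimnames(d) <- NULL
  attr(d, "metric_kind") <- if (mode == "hop") "hop" else "weighted-length"
  class(d) <- c("spdm", class(d))
  d
}

#' Nodes within a hop radius of an origin
#'
#' The BFS ball: all nodes at hop distance at most `depth` from `origin`,
#' origin included.
#'
#' @param g a [spatial_graph].
#' @param origin node index.
#' @param depth nonnegative integer radius.
#' @return Integer vector of node indices (sorted).
#' @export
bfs_ball <- function(g, origin, depth) {
  origin <- as.integer(origin)
  if (origin < 1L || origin > g$n) stop("'origin' is not a node of the graph")
  if (depth < 0) stop("'depth' must be nonnegative")
  d <- igraph::distances(sg_igraph(g), v = origin, weights = NA)[1L, ]
  which(d <= depth)
}

#' BFS ball-growth curve
#'
#' For depths `1..max_depth`, counts the nodes within each hop radius of the
#' origin (origin included, so the count at depth 1 is `degree(origin) + 1`).
#' The log-log slope of this curve against depth is the basis of the network
#' dimension estimate (see [estimate_dimension()]).
#'
#' @param g a [spatial_graph].
#' @param origin node index.
#' @param max_depth maximum depth; `NULL` uses the origin's eccentricity.
#' @return A data frame of class `"ball_growth"` with columns `depth` and
#'   `nodes` (cumulative counts, nondecreasing).
#' @export
ball_growth <- function(g, origin, max_depth = NULL) {
  origin <- as.integer(origin)
  if (origin < 1L || origin > g$n) stop("'origin' is not a node of the graph")
  d <- igraph::distances(sg_igraph(g), v = origin, weights = NA)[1L, ]
  d <- d[is.finite(d)]
  ecc <- max(d)
  if (is.null(max_depth)) max_depth <- ecc
  if (max_depth < 1) stop("'max_depth' must be at least 1")
  depths <- seq_len(max_depth)
  counts <- cumsum(tabulate(d + 1L, nbins = max(max_depth, ecc) + 1L))
  out <- data.frame(depth = depths,
                    nodes = counts[pmin(depths, ecc) + 1L])
  attr(out, "origin") <- origin
  class(out) <- c("ball_growth", class(out))
  out
}

#' Closeness centrality
#'
#' \eqn{C_i = 1 / \sum_j d'_{ij}} with hop distances. Central nodes minimise
#' boundary effects and are used as BFS origins for the dimension estimate.
#'
#' @param g a connected [spatial_graph].
#' @return Numeric vector of length `N`.
#' @export
closeness_centrality <- function(g) {
  comps <- igraph::components(sg_igraph(g))
  if (comps$no != 1L) {
    stop(sprintf("closeness requires a connected graph (%d components)", comps$no))
  }
  as.numeric(igraph::closeness(sg_igraph(g), weights = NA, normalized = FALSE))
}

#' Select central BFS origins
#'
#' Returns the nodes with highest closeness centrality: the top `fraction`
#' of nodes, clamped between `hard_min` and `soft_max` (and never more than
#' `N`). Ties in closeness are broken by ascending node index so that origin
#' selection is deterministic.
#'
#' @param g a connected [spatial_graph].
#' @param fraction fraction of nodes to take (default 1%).
#' @param hard_min minimum number of origins (default 10).
#' @param soft_max maximum number of origins (default 100).
#' @return Integer vector of node indices, descending closeness.
#' @export
select_central_origins <- function(g, fraction = 0.01, hard_min = 10L,
                                   soft_max = 100L) {
  k <- min(max(ceiling(fraction * g$n), hard_min), soft_max, g$n)
  cc <- closeness_centrality(g)
  order(-cc, seq_len(g$n))[seq_len(k)]
}

#' BFS-sampled subgraph
#'
#' Runs a BFS from `origin` until at least `node_cap` nodes are discovered,
#' completing the final depth shell (the result may slightly exceed the cap
#' rather than truncate arbitrarily within a shell), and returns the induced
#' subgraph. Used to keep shortest-path and eigendecomposition costs bounded
#' on large networks.
#'
#' @param g a [spatial_graph].
#' @param origin node index.
#' @param node_cap target node count (at least 1).
#' @return A connected [spatial_graph]; attribute `"mapping"` gives the
#'   original indices of the retained nodes.
#' @export
sample_subgraph <- function(g, origin, node_cap) {
  origin <- as.integer(origin)
  if (origin < 1L || origin > g$n) stop("'origin' is not a node of the graph")
  if (node_cap < 1) stop("'node_cap' must be at least 1")
  d <- igraph::distances(sg_igraph(g), v = origin, weights = NA)[1L, ]
  reach <- which(is.finite(d))
  if (length(reach) <= node_cap) {
    nodes <- reach
  } else {
    counts <- cumsum(tabulate(d[reach] + 1L))
    depth <- which(counts >= node_cap)[1L] - 1L  # complete this shell
    nodes <- reach[d[reach] <= depth]
  }
  sg_induced(g, sort(nodes))
}
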