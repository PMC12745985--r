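#' Spatial constant of a graph
#'
#' The dimensionless spatial constant
#' \eqn{S = \langle d' \rangle (\langle k \rangle / N)^{1/D}} relates the
#' mean shortest-path distance of a network to its size, in analogy with the
#' mean line segment of a Euclidean region (for a disk,
#' \eqn{\langle d \rangle \approx 0.9 r}, giving the constant
#' \eqn{0.9/\sqrt{\pi}}). For a spatially coherent network `S` is stable
#' across scales; shortcut (false) edges make the mean path length grow too
#' slowly with size and the constant fall with depth.
#'
#' @param g a connected [spatial_graph].
#' @param dim physical dimension `D` (default 2).
#' @param spdm optional precomputed [shortest_path_matrix()] of `g`.
#' @return Scalar `S`.
#' @export
spatial_constant <- function(g, dim = 2L, spdm = NULL) {
  if (is.null(spdm)) spdm <- shortest_path_matrix(g)
  n <- g$n
  mean_d <- sum(spdm) / (n * (n - 1))
  mean_d * (mean_degree(g) / n)^(1 / dim)
}

#' Spatial-constant profile across scales
#'
#' Samples the network at growing scales: from each of `n_origins` random
#' origin nodes, BFS subgraphs of increasing depth are extracted (up to half
#' the network diameter) and the spatial constant of each subgraph is
#' computed. A flat profile across depth indicates spatial coherence; a
#' profile that falls with depth indicates shortcut edges. Origins are fixed
#' across depths for a given seed.
#'
#' @param g a connected [spatial_graph] (largest component used otherwise).
#' @param dim physical dimension `D`.
#' @param n_origins number of random origins (default 10).
#' @param depths integer vector of BFS depths; `NULL` uses
#'   `2..ceiling(diameter/2)`.
#' @param min_size subgraphs smaller than this are skipped with a warning.
#' @param seed integer seed for origin selection.
#' @return Object of class `"spatial_constant_profile"`: data frame with
#'   per-depth averages of `nodes`, `mean_degree`, `mean_distance` and the
#'   spatial constant `s`.
#' @export
spatial_constant_profile <- function(g, dim = 2L, n_origins = 10L,
                                     depths = NULL, min_size = 10L,
                                     seed = 1L) {
  g <- largest_component(g)
  ig <- sg_igraph(g)
  if (is.null(depths)) {
    diam <- igraph::diameter(ig, weights = NA)
    depths <- seq(2L, max(2L, ceiling(diam / 2)))
  }
  set.seed(seed)
  origins <- sample.int(g$n, min(n_origins, g$n))
  dm <- igraph::distances(ig, v = origins, weights = NA)

  rows <- list()
  skipped <- 0L
  for (r in depths) {
    vals <- matrix(NA_real_, length(origins), 4L)
    for (i in seq_along(origins)) {
      nodes <- which(dm[i, ] <= r)
      if (length(nodes) < min_size) { skipped <- skipped + 1L; next }
      sub <- sg_induced(g, nodes)
      if (n_components(sub) != 1L) next  # cannot happen for BFS balls
      spd <- shortest_path_matrix(sub)
      nsub <- sub$n
      mean_d <- sum(spd) / (nsub * (nsub - 1))
      kbar <- mean_degree(sub)
      vals[i, ] <- c(nsub, kbar, mean_d, mean_d * (kbar / nsub)^(1 / dim))
    }
    ok <- stats::complete.cases(vals)
    if (!any(ok)) next
    rows[[length(rows) + 1L]] <- data.frame(
      depth = r,
      nodes = mean(vals[ok, 1L]),
      mean_degree = mean(vals[ok, 2L]),
      mean_distance = mean(vals[ok, 3L]),
      s = mean(vals[ok, 4L])
    )
  }
  if (skipped > 0L) {
    warning(sprintf("%d origin/depth subgraphs below %d nodes were skipped",
                    skipped, min_size))
  }
  if (!length(rows)) stop("no depth produced a usable subgraph")
  out <- do.call(rbind, rows)
  attr(out, "target_dim") <- dim
  attr(out, "origins") <- origins
  class(out) <- c("spatial_constant_profile", class(out))
  out
}

#' @export
print.spatial_constant_profile <- function(x, ...) {
  cat(sprintf("Spatial-constant profile (D = %d, %d depths)\n",
              attr(x, "target_dim"), nrow(x)))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Euclidean spatial constant of a point set
#'
#' The Euclidean counterpart \eqn{\beta = \langle d \rangle (\rho/N)^{1/D}}
#' of the network spatial constant, computed directly from coordinates with
#' \eqn{\rho = N / \mathrm{volume}}; for uniform points in a disk it
#' approaches \eqn{0.9/\sqrt{\pi} \approx 0.508}.
#'
#' @param points numeric matrix of coordinates (rows = points).
#' @param dim dimension `D` (default `ncol(points)`).
#' @param volume volume (area in 2D) of the supporting region; `NULL`
#'   estimates it from the bounding box.
#' @param max_pairs pairwise distances are averaged over at most this many
#'   random pairs (seeded) when the exact count exceeds it.
#' @param seed seed for pair sampling.
#' @return Scalar \eqn{\beta}.
#' @export
euclidean_spatial_constant <- function(points, dim = ncol(points),
                                       volume = NULL, max_pairs = 1e6,
                                       seed = 1L) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2L) stop("need at least 2 points")
  mean_d <- mean_pairwise_distance(points, max_pairs = max_pairs, seed = seed)
  if (is.null(volume)) {
    volume <- prod(apply(points, 2L, function(z) diff(range(z))))
  }
  rho <- n / volume
  mean_d * (rho / n)^(1 / dim)
}

# Mean pairwise Euclidean distance; exact when the number of pairs is
# small, Monte Carlo over random pairs otherwise.
mean_pairwise_distance <- function(points, max_pairs = 1e6, seed = 1L) {
  n <- nrow(points)
  npairs <- n * (n - 1) / 2
  if (npairs <= max_pairs) return(mean(stats::dist(points)))
  set.seed(seed)
  i <- sample.int(n, max_pairs, replace = TRUE)
  j <- sample.int(n - 1L, max_pairs, replace = TRUE)
  j <- ifelse(j >= i, j + 1L, j)  # uniform over ordered pairs, i != j
  mean(sqrt(rowSums((points[i, , drop = FALSE] - points[j, , drop = FALSE])^2)))
}

#' Coefficient of determination between Euclidean and network distances
#'
#' Regresses ground-truth Euclidean pairwise distances on shortest-path
#' distances over (up to `max_pairs`) node pairs and returns the \eqn{R^2}.
#' A spatially coherent network shows a strong linear relation; false edges
#' break it.
#'
#' @param g a connected [spatial_graph] with ground-truth positions.
#' @param max_pairs maximum number of node pairs (default 1e6; all pairs
#'   when fewer).
#' @param seed seed for pair sampling.
#' @return Scalar \eqn{R^2} in \eqn{[0,1]}.
#' @export
distance_correlation_r2 <- function(g, max_pairs = 1e6, seed = 1L) {
  if (is.null(g$positions)) stop("ground-truth positions are required")
  g <- largest_component(g)
  n <- g$n
  npairs <- n * (n - 1) / 2
  if (npairs <= max_pairs) {
    spd <- shortest_path_matrix(g)
    idx <- which(upper.tri(spd))
    x <- spd[idx]
    eu <- as.matrix(stats::dist(g$positions))
    y <- eu[idx]
  } else {
    set.seed(seed)
    i <- sample.int(n, max_pairs, replace = TRUE)
    j <- sample.int(n - 1L, max_pairs, replace = TRUE)
    j <- ifelse(j >= i, j + 1L, j)
    # distances from the (distinct) source nodes only
    src <- sort(unique(i))
    dm <- igraph::distances(sg_igraph(g), v = src, weights = NA)
    x <- dm[cbind(match(i, src), j)]
    y <- sqrt(rowSums((g$positions[i, , drop = FALSE] -
                         g$positions[j, , drop = FALSE])^2))
  }
  stats::cor(x, y)^2
}
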