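#' Gram matrix from a distance matrix by double centering
#'
#' Applies the classical-MDS double-centering transform
#' \eqn{G = -\tfrac12 J D^2 J} with \eqn{J = I - \tfrac1N 1 1^T} to a
#' distance matrix (Euclidean or shortest-path). For an exact Euclidean
#' distance matrix of points in `D` dimensions, `G` is the Gram matrix of
#' the centred coordinates and has rank at most `D`; for a shortest-path
#' distance matrix, the spectrum of `G` measures how Euclidean-like the
#' network metric is.
#'
#' @param d a square symmetric distance matrix (e.g. from
#'   [shortest_path_matrix()]).
#' @return Symmetric matrix `G` with rows summing to zero.
#' @examples
#' gram_from_distances(rbind(c(0, 2), c(2, 0)))  # [[1,-1],[-1,1]]
#' @export
gram_from_distances <- function(d) {
  d <- unclass(as.matrix(d))
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  d2 <- d * d
  rm <- rowMeans(d2)
  g <- -0.5 * (d2 - outer(rm, rep(1, ncol(d2))) -
                 outer(rep(1, nrow(d2)), colMeans(d2)) + mean(d2))
  (g + t(g)) / 2
}

#' Spectral coherence scores of a Gram matrix
#'
#' Computes the eigenvalue spectrum of the Gram matrix and two coherence
#' scores: the variance contribution
#' \eqn{C_D = \sum_{i \le D} \lambda_i / \sum_j \lambda_j} of the first `D`
#' eigenvalues, and the spectral gap
#' \eqn{\Delta\lambda = 1 - \lambda_{D+1}/\lambda_D}. Both equal 1 when the
#' distances come from exact `D`-dimensional Euclidean coordinates and drop
#' as the network metric departs from Euclidean behaviour.
#'
#' Shortest-path metrics are generally non-Euclidean, so the Gram matrix has
#' negative eigenvalues and the denominator convention matters. The default
#' `"all"` divides by the plain eigenvalue sum (the trace of `G`), the
#' literal form of the score; it can exceed 1 on strongly non-Euclidean
#' input. `"positive"` divides by the nonnegative part of the spectrum and
#' stays in \eqn{[0,1]}; `"abs"` divides by \eqn{\sum_j |\lambda_j|}.
#'
#' @param gram symmetric matrix from [gram_from_distances()] (or a numeric
#'   vector of eigenvalues, descending).
#' @param dim target embedding dimension `D` (default 2).
#' @param denominator `"all"` (default), `"positive"` or `"abs"`.
#' @return An object of class `"spectral_scores"`: list with `eigenvalues`
#'   (descending), `dim`, `variance_contribution`, `spectral_gap`
#'   (`NA` with a flag when \eqn{\lambda_D \le 0}).
#' @export
spectral_scores <- function(gram, dim = 2L,
                            denominator = c("all", "positive", "abs")) {
  denominator <- match.arg(denominator)
  if (is.matrix(gram)) {
    ev <- eigen(gram, symmetric = TRUE, only.values = TRUE)$values
  } else {
    ev <- sort(as.numeric(gram), decreasing = TRUE)
  }
  dim <- as.integer(dim)
  if (dim < 1L || dim >= length(ev)) stop("'dim' must satisfy 1 <= dim < N")
  denom <- switch(denominator,
                  all = sum(ev),
                  positive = sum(pmax(ev, 0)),
                  abs = sum(abs(ev)))
  cd <- if (denom > 0) sum(ev[seq_len(dim)]) / denom else NA_real_
  gap_defined <- ev[dim] > 0
  gap <- if (gap_defined) 1 - ev[dim + 1L] / ev[dim] else NA_real_
  structure(
    list(eigenvalues = ev, dim = dim, variance_contribution = cd,
         spectral_gap = gap, gap_defined = gap_defined,
         denominator = denominator),
    class = "spectral_scores"
  )
}

#' @export
print.spectral_scores <- function(x, ...) {
  cat(sprintf("Spectral coherence scores (D = %d)\n", x$dim))
  cat(sprintf("  variance contribution C_D: %.4f\n", x$variance_contribution))
  if (x$gap_defined) {
    cat(sprintf("  spectral gap           dl: %.4f\n", x$spectral_gap))
  } else {
    cat("  spectral gap: undefined (lambda_D <= 0)\n")
  }
  k <- min(5L, length(x$eigenvalues))
  cat("  leading eigenvalues:",
      paste(signif(x$eigenvalues[seq_len(k)], 4), collapse = ", "), "\n")
  invisible(x)
}

#' Classical MDS coordinates from a Gram matrix
#'
#' Embeds the nodes in `dim` dimensions using the top eigenvectors of the
#' Gram matrix scaled by the square roots of their (nonnegative-clipped)
#' eigenvalues. On an exact Euclidean distance matrix this recovers the
#' original coordinates up to rotation, reflection and translation; on a
#' shortest-path Gram matrix it gives a topology-only reconstruction.
#'
#' @param gram double-centered symmetric matrix from
#'   [gram_from_distances()].
#' @param dim embedding dimension.
#' @return `N x dim` coordinate matrix with centroid at the origin.
#' @export
reconstruct_classical_mds <- function(gram, dim = 2L) {
  dim <- as.integer(dim)
  es <- eigen(gram, symmetric = TRUE)
  ev <- es$values[seq_len(dim)]
  if (any(ev <= 0)) {
    warning("fewer than 'dim' positive eigenvalues; padding with zeros")
  }
  coords <- es$vectors[, seq_len(dim), drop = FALSE] %*%
    diag(sqrt(pmax(ev, 0)), nrow = dim)
  coords
}

#' Spectral scores of a graph
#'
#' Convenience wrapper: shortest-path distance matrix, double centering and
#' [spectral_scores()] in one call. Networks larger than `node_cap` are
#' first reduced by [sample_subgraph()] from the most central node, keeping
#' the eigendecomposition tractable.
#'
#' @param g a [spatial_graph] (largest component used if disconnected).
#' @param dim target dimension.
#' @param node_cap BFS sampling cap for large graphs (default 3000).
#' @param mode distance mode passed to [shortest_path_matrix()].
#' @param denominator passed to [spectral_scores()].
#' @return A `"spectral_scores"` object.
#' @export
graph_spectral_scores <- function(g, dim = 2L, node_cap = 3000L,
                                  mode = c("hop", "weighted"),
                                  denominator = c("all", "positive", "abs")) {
  mode <- match.arg(mode)
  g <- largest_component(g)
  if (g$n > node_cap) {
    cc <- closeness_centrality(g)
    g <- sample_subgraph(g, which.max(cc), node_cap)
  }
  spd <- shortest_path_matrix(g, mode = mode)
  spectral_scores(gram_from_distances(spd), dim = dim,
                  denominator = match.arg(denominator))
}
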