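# Independent oracles used across the suite. These deliberately use naive
# algorithms (cubic loops, exhaustive enumeration) so they share no code
# path with the package implementation.

# Floyd-Warshall all-pairs shortest paths on an edge matrix (hop metric).
fw_spdm <- function(edges, n) {
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    d[i, j] <- 1; d[j, i] <- 1
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# Exhaustive count of simple paths with exactly L edges between u and v:
# enumerate every ordered tuple of L-1 distinct interior nodes drawn from
# V \ {u, v} and check chain adjacency.
enum_indirect_paths <- function(edges, n, u, v, L) {
  amat <- matrix(FALSE, n, n)
  for (r in seq_len(nrow(edges))) {
    amat[edges[r, 1], edges[r, 2]] <- TRUE
    amat[edges[r, 2], edges[r, 1]] <- TRUE
  }
  interior <- setdiff(seq_len(n), c(u, v))
  k <- L - 1
  if (length(interior) < k) return(0L)
  tuples <- ordered_tuples(interior, k)
  count <- 0L
  for (tp in tuples) {
    chain <- c(u, tp, v)
    ok <- TRUE
    for (s in seq_len(L)) {
      if (!amat[chain[s], chain[s + 1]]) { ok <- FALSE; break }
    }
    if (ok) count <- count + 1L
  }
  count
}

ordered_tuples <- function(pool, k) {
  if (k == 0) return(list(integer()))
  out <- list()
  for (i in seq_along(pool)) {
    for (rest in ordered_tuples(pool[-i], k - 1)) {
      out[[length(out) + 1]] <- c(pool[i], rest)
    }
  }
  out
}

# Random connected simple graph (rejection over G(n, p)).
random_connected_graph <- function(n, p = 0.25, seed = 1) {
  set.seed(seed)
  repeat {
    pairs <- t(combn(n, 2))
    keep <- runif(nrow(pairs)) < p
    if (sum(keep) < n - 1) next
    edges <- pairs[keep, , drop = FALSE]
    if (all(is.finite(fw_spdm(edges, n)))) {
      return(spatial_graph(edges, n = n))
    }
  }
}

# RMS coordinate error after optimal rotation/reflection/translation/scale.
procrustes_rms <- function(X, Y) {
  pr <- vegan::procrustes(X, Y, symmetric = FALSE)
  sqrt(mean((pr$Yrot - pr$X)^2))
}

# Small 2D lattice graph, nodes indexed row-major.
lattice_graph <- function(nside) {
  idx <- function(i, j) (i - 1) * nside + j
  E <- rbind(
    cbind(as.vector(outer(1:(nside - 1), 1:nside, idx)),
          as.vector(outer(2:nside, 1:nside, idx))),
    cbind(as.vector(outer(1:nside, 1:(nside - 1), idx)),
          as.vector(outer(1:nside, 2:nside, idx))))
  spatial_graph(E, n = nside^2)
}

ring_graph <- function(n) {
  spatial_graph(cbind(seq_len(n), c(seq_len(n)[-1], 1)))
}
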