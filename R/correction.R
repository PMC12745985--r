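#' Rank edges by interaction weight
#'
#' Confidence score = raw edge weight: heavier edges (more observed
#' interactions) are more likely to reflect genuine proximity. Ties are
#' broken by ascending canonical edge order so the ranking is deterministic;
#' an all-equal weight distribution is flagged as low-discriminability.
#'
#' @param g a weighted [spatial_graph].
#' @return An `"edge_ranking"`: list with `edges` (two-column matrix in
#'   descending score order), `scores`, `method`.
#' @export
score_by_weight <- function(g) {
  if (is.null(g$weights)) stop("edge weights are required")
  ord <- order(-g$weights, g$edges[, 1L], g$edges[, 2L])
  rk <- structure(
    list(edges = g$edges[ord, , drop = FALSE], scores = g$weights[ord],
         method = "weight"),
    class = "edge_ranking"
  )
  if (length(unique(g$weights)) == 1L) {
    attr(rk, "low_discriminability") <- TRUE
    warning("all edge weights are equal; weight ranking carries no information")
  }
  rk
}

#' Rank edges by indirect-path support
#'
#' Scores each edge `(u, v)` by the number of simple paths of exactly `L`
#' edges between `u` and `v` in the graph with the direct edge removed
#' (interior nodes distinct and different from `u`, `v`). True spatial
#' neighbours sit in densely interconnected neighbourhoods and are backed by
#' many such detours; spurious shortcuts are not. For the default `L = 3`
#' the count is the number of edges joining a neighbour of `u` to a
#' neighbour of `v`.
#'
#' @param g a [spatial_graph].
#' @param L path length in edges (default 3, minimum 2).
#' @return An `"edge_ranking"` (descending score; ties broken by canonical
#'   edge order).
#' @export
score_by_indirect_paths <- function(g, L = 3L) {
  L <- as.integer(L)
  if (L < 2L) stop("'L' must be at least 2")
  m <- nrow(g$edges)
  adj <- adjacency_sets(g)
  scores <- numeric(m)
  if (L == 2L) {
    for (e in seq_len(m)) {
      u <- g$edges[e, 1L]; v <- g$edges[e, 2L]
      scores[e] <- length(setdiff(intersect(adj[[u]], adj[[v]]), c(u, v)))
    }
  } else if (L == 3L) {
    amat <- adjacency_logical(g)
    for (e in seq_len(m)) {
      u <- g$edges[e, 1L]; v <- g$edges[e, 2L]
      a <- setdiff(adj[[u]], c(u, v))
      b <- setdiff(adj[[v]], c(u, v))
      if (!length(a) || !length(b)) next
      # edges between N(u) and N(v); the diagonal (a == b) is never
      # adjacent to itself, so distinct interior nodes come for free
      scores[e] <- sum(amat[a, b, drop = FALSE])
    }
  } else {
    for (e in seq_len(m)) {
      u <- g$edges[e, 1L]; v <- g$edges[e, 2L]
      scores[e] <- count_simple_paths(adj, u, v, L)
    }
  }
  ord <- order(-scores, g$edges[, 1L], g$edges[, 2L])
  structure(
    list(edges = g$edges[ord, , drop = FALSE], scores = scores[ord],
         method = "indirect_path", L = L),
    class = "edge_ranking"
  )
}

adjacency_sets <- function(g) {
  adj <- vector("list", g$n)
  for (e in seq_len(nrow(g$edges))) {
    i <- g$edges[e, 1L]; j <- g$edges[e, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

adjacency_logical <- function(g) {
  amat <- matrix(FALSE, g$n, g$n)
  amat[g$edges] <- TRUE
  amat[g$edges[, 2:1, drop = FALSE]] <- TRUE
  amat
}

# DFS count of simple u->v paths with exactly L edges whose interior nodes
# are distinct and avoid u and v; with L >= 2 the direct edge (u,v) can
# never be part of such a path.
count_simple_paths <- function(adj, u, v, L) {
  if (L < 2L) return(0L)
  recurse <- function(node, steps, visited) {
    total <- 0L
    for (nxt in adj[[node]]) {
      if (nxt == v) {
        if (steps + 1L == L) total <- total + 1L
        next
      }
      if (steps + 1L >= L) next        # would overshoot before reaching v
      if (nxt == u || nxt %in% visited) next
      total <- total + recurse(nxt, steps + 1L, c(visited, nxt))
    }
    total
  }
  recurse(u, 0L, integer())
}

#' @export
print.edge_ranking <- function(x, ...) {
  cat(sprintf("Edge ranking (%s): %d edges, scores %.3g .. %.3g\n",
              x$method, nrow(x$edges),
              if (length(x$scores)) max(x$scores) else NA,
              if (length(x$scores)) min(x$scores) else NA))
  invisible(x)
}

#' Keep the top fraction of ranked edges
#'
#' Retains the first `round(tau * |E|)` edges of the ranking (round half
#' up); nodes are kept, so isolated nodes may appear.
#'
#' @param g a [spatial_graph].
#' @param ranking an `"edge_ranking"` of `g`'s edges.
#' @param tau retention fraction in `[0, 1]`.
#' @return A [spatial_graph] with the retained edge set.
#' @export
filter_graph <- function(g, ranking, tau) {
  if (tau < 0 || tau > 1) stop("'tau' must lie in [0, 1]")
  m <- nrow(ranking$edges)
  keep_n <- min(m, floor(tau * m + 0.5))
  kept <- ranking$edges[seq_len(keep_n), , drop = FALSE]
  # carry attributes of the kept edges over from the original graph
  idx <- match(edge_key(kept, g$n), edge_key(g$edges, g$n))
  spatial_graph(kept, n = g$n,
                weights = g$weights[idx], lengths = g$lengths[idx],
                positions = g$positions, parts = g$parts, ids = g$ids)
}

#' Golden-section maximisation on an interval
#'
#' Maximises `f` on `[lower, upper]` with the golden-section rule: internal
#' points \eqn{x_1 = b - (b-a)/\phi}, \eqn{x_2 = a + (b-a)/\phi},
#' \eqn{\phi = (1+\sqrt5)/2}, keeping the half-interval containing the
#' higher value. Stops when the interval is narrower than `tol` or after
#' `max_iter` iterations. The objective is assumed unimodal; every
#' evaluation is logged.
#'
#' @param f scalar function to maximise.
#' @param lower,upper interval bounds.
#' @param tol minimum interval width (default 0.01).
#' @param max_iter maximum iterations (default 50).
#' @return List with `x` (argmax), `value`, `trace` (data frame of `x`,
#'   `value` in evaluation order).
#' @export
golden_section_max <- function(f, lower = 0, upper = 1, tol = 0.01,
                               max_iter = 50L) {
  phi <- (1 + sqrt(5)) / 2
  a <- lower; b <- upper
  xs <- c(); vs <- c()
  eval_f <- function(x) {
    v <- f(x)
    if (!is.finite(v)) v <- -Inf
    xs <<- c(xs, x); vs <<- c(vs, v)
    v
  }
  x1 <- b - (b - a) / phi
  x2 <- a + (b - a) / phi
  f1 <- eval_f(x1); f2 <- eval_f(x2)
  iter <- 0L
  while ((b - a) > tol && iter < max_iter) {
    iter <- iter + 1L
    if (f1 >= f2) {
      b <- x2
      x2 <- x1; f2 <- f1
      x1 <- b - (b - a) / phi
      f1 <- eval_f(x1)
    } else {
      a <- x1
      x1 <- x2; f1 <- f2
      x2 <- a + (b - a) / phi
      f2 <- eval_f(x2)
    }
  }
  best <- which.max(vs)
  list(x = xs[best], value = vs[best],
       trace = data.frame(x = xs, value = vs))
}

#' Coherence-driven filter optimisation
#'
#' The denoising loop: given an edge-confidence ranking, finds the retention
#' fraction \eqn{\tau^*} that maximises the spatial-coherence score
#' \eqn{S(\tau)} — the variance contribution \eqn{C_D} of the Gram matrix of
#' the filtered graph (largest component, BFS-sampled above `node_cap`) —
#' by golden-section search on \eqn{\tau \in [0, 1]} (interval width 0.01,
#' at most 50 iterations). A \eqn{\tau} whose filtered graph collapses
#' scores \eqn{-\infty} and the search continues.
#'
#' @param g a [spatial_graph].
#' @param ranking an `"edge_ranking"` from [score_by_weight()] or
#'   [score_by_indirect_paths()].
#' @param dim target dimension for the coherence score (default 2).
#' @param tol minimum interval width (default 0.01).
#' @param max_iter iteration cap (default 50).
#' @param node_cap sampling cap for the spectral score.
#' @param objective test seam: replaces the coherence objective by an
#'   arbitrary `function(tau)`; used to validate the search itself.
#' @return Object of class `"filter_result"`: list with `tau_star`,
#'   `filtered_graph`, `s0`, `s_star`, `delta_s`, `evaluations`, `removed`
#'   (edges dropped at `tau_star`), `ranking_method`.
#' @export
optimize_filter <- function(g, ranking, dim = 2L, tol = 0.01, max_iter = 50L,
                            node_cap = 3000L, objective = NULL) {
  if (is.null(objective)) {
    objective <- function(tau) {
      gt <- filter_graph(g, ranking, tau)
      if (nrow(gt$edges) < 1L) return(-Inf)
      comp <- suppressWarnings(largest_component(gt))
      if (comp$n <= dim + 1L) return(-Inf)
      sc <- tryCatch(
        graph_spectral_scores(comp, dim = dim, node_cap = node_cap),
        error = function(e) NULL)
      if (is.null(sc)) return(-Inf)
      sc$variance_contribution
    }
  }
  s0 <- objective(1)
  gs <- golden_section_max(objective, 0, 1, tol = tol, max_iter = max_iter)
  tau_star <- gs$x
  filtered <- filter_graph(g, ranking, tau_star)
  kept_keys <- edge_key(filtered$edges, g$n)
  removed <- g$edges[!(edge_key(g$edges, g$n) %in% kept_keys), , drop = FALSE]
  structure(
    list(tau_star = tau_star, filtered_graph = filtered,
         s0 = s0, s_star = gs$value, delta_s = gs$value - s0,
         evaluations = gs$trace, removed = removed,
         ranking_method = ranking$method),
    class = "filter_result"
  )
}

#' @export
print.filter_result <- function(x, ...) {
  cat("Coherence-driven edge filter\n")
  cat(sprintf("  ranking: %s\n", x$ranking_method))
  cat(sprintf("  tau* = %.4f  (kept %d edges, removed %d)\n",
              x$tau_star, nrow(x$filtered_graph$edges), nrow(x$removed)))
  cat(sprintf("  S0 = %.4f -> S(tau*) = %.4f  (delta S = %+.4f)\n",
              x$s0, x$s_star, x$delta_s))
  cat(sprintf("  %d objective evaluations\n", nrow(x$evaluations)))
  invisible(x)
}
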