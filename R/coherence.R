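#' Fit the spatial-coherence diagnostics of a network
#'
#' The main entry point of the package: computes the three topology-only
#' spatial-coherence diagnostics of a graph in one call —
#' \itemize{
#'   \item the spectral scores (variance contribution \eqn{C_D} and spectral
#'     gap \eqn{\Delta\lambda}) of the double-centered shortest-path Gram
#'     matrix ([graph_spectral_scores()]),
#'   \item the intrinsic network dimension from BFS ball growth
#'     ([estimate_dimension()]),
#'   \item the spatial-constant profile across scales
#'     ([spatial_constant_profile()]).
#' }
#' The three are deliberately independent: `dim` is the expected physical
#' dimension supplied by the user (default 2), not the estimated one.
#'
#' @param g a [spatial_graph]; if disconnected, the largest component is
#'   used with a warning (error when `strict = TRUE`).
#' @param dim expected physical dimension `D` (default 2).
#' @param seed seed for the random origins of the spatial-constant profile.
#' @param node_cap sampling cap for the spectral computation.
#' @param n_origins random origins for the spatial-constant profile.
#' @param mode distance mode, `"hop"` or `"weighted"`.
#' @param strict error on disconnected input instead of taking the largest
#'   component.
#' @return Object of class `"spatial_coherence"`: list with components
#'   `spectral`, `dimension`, `spatial_constant`, `graph_summary`, `dim`,
#'   `seed`.
#' @examples
#' \donttest{
#' net <- generate_network(n = 600, seed = 1)
#' fit <- spatial_coherence(net, dim = 2, seed = 1)
#' fit
#' }
#' @export
spatial_coherence <- function(g, dim = 2L, seed = 1L, node_cap = 3000L,
                              n_origins = 10L, mode = c("hop", "weighted"),
                              strict = FALSE) {
  mode <- match.arg(mode)
  g <- largest_component(g, strict = strict)
  spectral <- graph_spectral_scores(g, dim = dim, node_cap = node_cap,
                                    mode = mode)
  dimension <- estimate_dimension(g)
  profile <- spatial_constant_profile(g, dim = dim, n_origins = n_origins,
                                      seed = seed)
  structure(
    list(spectral = spectral, dimension = dimension,
         spatial_constant = profile,
         graph_summary = list(n = g$n, m = nrow(g$edges),
                              mean_degree = mean_degree(g)),
         dim = as.integer(dim), seed = as.integer(seed)),
    class = "spatial_coherence"
  )
}

#' @export
print.spatial_coherence <- function(x, ...) {
  gs <- x$graph_summary
  cat(sprintf("Spatial coherence (D = %d) of a graph with %d nodes, %d edges\n",
              x$dim, gs$n, gs$m))
  cat(sprintf("  variance contribution C_D : %.4f\n",
              x$spectral$variance_contribution))
  if (x$spectral$gap_defined) {
    cat(sprintf("  spectral gap           dl : %.4f\n", x$spectral$spectral_gap))
  } else {
    cat("  spectral gap              : undefined (lambda_D <= 0)\n")
  }
  cat(sprintf("  network dimension      D' : %.3f (sd %.3f)\n",
              x$dimension$dimension, x$dimension$sd))
  s <- x$spatial_constant$s
  cat(sprintf("  spatial constant        S : %.4f at full depth (range %.4f-%.4f)\n",
              s[length(s)], min(s), max(s)))
  invisible(x)
}

#' @export
summary.spatial_coherence <- function(object, ...) {
  print(object)
  cat("\nSpatial-constant profile:\n")
  print.data.frame(object$spatial_constant, row.names = FALSE, digits = 4)
  invisible(object)
}

#' @export
coef.spatial_coherence <- function(object, ...) {
  c(variance_contribution = object$spectral$variance_contribution,
    spectral_gap = object$spectral$spectral_gap,
    network_dimension = object$dimension$dimension,
    spatial_constant = object$spatial_constant$s[nrow(object$spatial_constant)])
}

#' @export
plot.spatial_coherence <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(op))
  sc <- x$spatial_constant
  graphics::plot(sc$depth, sc$s, type = "b", pch = 16,
                 xlab = "BFS depth", ylab = "spatial constant S",
                 main = "Spatial constant")
  graphics::plot(sc$depth, sc$nodes, log = "xy", type = "b", pch = 16,
                 xlab = "BFS depth", ylab = "subgraph nodes",
                 main = sprintf("Ball growth (D' = %.2f)", x$dimension$dimension))
  ev <- x$spectral$eigenvalues
  k <- min(10L, length(ev))
  graphics::barplot(ev[seq_len(k)], names.arg = seq_len(k),
                    xlab = "eigenvalue rank", ylab = "eigenvalue",
                    main = sprintf("Gram spectrum (C_D = %.2f)",
                                   x$spectral$variance_contribution))
  invisible(x)
}

#' Serialize a coherence fit to JSON
#'
#' Writes the scores, spectrum (truncated to `max_eigenvalues`), dimension
#' fit and spatial-constant profile as versioned JSON that
#' [read_coherence_report()] loads back.
#'
#' @param x a `"spatial_coherence"` object.
#' @param path output file path.
#' @param max_eigenvalues eigenvalues retained in the report (default 50;
#'   `Inf` keeps all).
#' @return `path`, invisibly.
#' @export
write_coherence_report <- function(x, path, max_eigenvalues = 50L) {
  ev <- x$spectral$eigenvalues
  if (is.finite(max_eigenvalues)) ev <- ev[seq_len(min(length(ev), max_eigenvalues))]
  rep <- list(
    schema = "spatialcoherence/coherence-report",
    version = 1L,
    dim = x$dim,
    seed = x$seed,
    graph = x$graph_summary,
    spectral = list(
      variance_contribution = x$spectral$variance_contribution,
      spectral_gap = x$spectral$spectral_gap,
      gap_defined = x$spectral$gap_defined,
      denominator = x$spectral$denominator,
      eigenvalues = ev
    ),
    dimension = list(
      pooled = x$dimension$dimension,
      sd = x$dimension$sd,
      r2 = x$dimension$r2,
      slopes = x$dimension$slopes
    ),
    spatial_constant = as.data.frame(unclass(x$spatial_constant))
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a coherence report written by [write_coherence_report()]
#'
#' @param path JSON file path.
#' @return The report as a list.
#' @export
read_coherence_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(rep$schema, "spatialcoherence/coherence-report")) {
    stop("not a coherence report: ", path)
  }
  rep
}
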