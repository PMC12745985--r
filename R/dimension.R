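#' Estimate the intrinsic network dimension
#'
#' In a spatially coherent network the number of nodes within a BFS radius
#' grows as a power of the radius, \eqn{N \propto r'^{D'}}, with exponent
#' the dimension of the underlying physical space. For each origin the
#' log-log ball-growth curve is fitted over the sliding window of depths
#' with the highest coefficient of determination, and the per-origin slopes
#' are pooled by their arithmetic mean.
#'
#' Origins should be central nodes (high closeness) to minimise boundary
#' effects; by default they come from [select_central_origins()].
#'
#' @param g a connected [spatial_graph] (largest component used otherwise).
#' @param origins integer vector of origin nodes; `NULL` selects central
#'   origins automatically.
#' @param max_depth maximum BFS depth per origin; `NULL` uses each origin's
#'   eccentricity.
#' @param window_frac sliding-window length as a fraction of the available
#'   depths (minimum window of 5 points).
#' @return Object of class `"dimension_estimate"`: list with
#'   `dimension` (pooled slope), `sd` (across origins), `r2` (mean best
#'   \eqn{R^2}), `slopes`, `windows`, `origins`.
#' @examples
#' ring <- spatial_graph(cbind(1:100, c(2:100, 1)))
#' estimate_dimension(ring)$dimension  # ~1
#' @export
estimate_dimension <- function(g, origins = NULL, max_depth = NULL,
                               window_frac = 0.5) {
  g <- largest_component(g)
  if (is.null(origins)) origins <- select_central_origins(g)
  if (!length(origins)) stop("'origins' must be nonempty")

  # all origin BFS distances in one sparse-graph call
  dm <- igraph::distances(sg_igraph(g), v = origins, weights = NA)
  slopes <- numeric(length(origins))
  r2s <- numeric(length(origins))
  windows <- matrix(NA_integer_, length(origins), 2L,
                    dimnames = list(NULL, c("start", "end")))
  for (i in seq_along(origins)) {
    d <- dm[i, ]
    ecc <- max(d)
    md <- if (is.null(max_depth)) ecc else min(max_depth, ecc)
    if (md < 3) stop("fewer than 3 usable depths; graph too small or too dense")
    counts <- cumsum(tabulate(d + 1L, nbins = ecc + 1L))
    nodes <- counts[seq_len(md) + 1L]
    fit <- best_window_fit(log(seq_len(md)), log(nodes), window_frac)
    slopes[i] <- fit$slope
    r2s[i] <- fit$r2
    windows[i, ] <- fit$window
  }
  structure(
    list(dimension = mean(slopes), sd = stats::sd(slopes), r2 = mean(r2s),
         slopes = slopes, windows = windows, origins = origins),
    class = "dimension_estimate"
  )
}

#' @export
print.dimension_estimate <- function(x, ...) {
  cat(sprintf("Network dimension: %.3f (sd %.3f over %d origins, mean R2 %.3f)\n",
              x$dimension, x$sd, length(x$slopes), x$r2))
  invisible(x)
}

# Best-R2 sliding-window linear fit of y on x. Windows are all contiguous
# runs of length max(5, ceiling(window_frac * n)); ties go to the earliest
# window. Returns slope, r2 and the window bounds (indices into x).
best_window_fit <- function(x, y, window_frac = 0.5, min_window = 5L) {
  n <- length(x)
  if (n < 3L) stop("need at least 3 points for a window fit")
  w <- min(n, max(min_window, ceiling(window_frac * n)))
  best <- list(slope = NA_real_, r2 = -Inf, window = c(NA, NA))
  for (s in seq_len(n - w + 1L)) {
    idx <- s:(s + w - 1L)
    xs <- x[idx]; ys <- y[idx]
    sxx <- sum((xs - mean(xs))^2)
    syy <- sum((ys - mean(ys))^2)
    if (sxx == 0 || syy == 0) next  # degenerate (flat) window
    sxy <- sum((xs - mean(xs)) * (ys - mean(ys)))
    slope <- sxy / sxx
    r2 <- sxy^2 / (sxx * syy)
    if (r2 > best$r2 + 1e-12) {
      best <- list(slope = slope, r2 = r2, window = c(s, s + w - 1L))
    }
  }
  if (!is.finite(best$r2)) {
    stop("no usable window: ball-growth curve is degenerate")
  }
  best
}
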