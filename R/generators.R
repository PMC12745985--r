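#' Sample uniform points in a simple region
#'
#' Ground-truth point clouds for synthetic networks: uniform samples in a
#' unit-radius disk or ball (the defaults in 2D and 3D), or in a unit square
#' or cube.
#'
#' @param n number of points.
#' @param shape `"disk"`, `"sphere"` (solid unit ball), `"square"` or
#'   `"cube"`.
#' @param radius radius of disk/sphere (side length for square/cube).
#' @param seed integer seed; identical seeds give identical coordinates.
#' @return `n x d` numeric matrix (`d` = 2 or 3).
#' @export
sample_points <- function(n, shape = c("disk", "sphere", "square", "cube"),
                          radius = 1, seed = 1L) {
  shape <- match.arg(shape)
  set.seed(seed)
  switch(shape,
    disk = {
      r <- radius * sqrt(stats::runif(n))
      th <- stats::runif(n, 0, 2 * pi)
      cbind(x = r * cos(th), y = r * sin(th))
    },
    sphere = {
      u <- matrix(stats::rnorm(3 * n), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      r <- radius * stats::runif(n)^(1 / 3)
      u * r
    },
    square = cbind(x = stats::runif(n, 0, radius), y = stats::runif(n, 0, radius)),
    cube = cbind(x = stats::runif(n, 0, radius), y = stats::runif(n, 0, radius),
                 z = stats::runif(n, 0, radius))
  )
}

#' K-nearest-neighbour proximity graph
#'
#' Builds the union-symmetrised KNN graph of a point cloud: nodes `i` and
#' `j` are joined when `i` is among the `k` nearest neighbours of `j` or
#' vice versa, so every node has degree at least `k`. In bipartite mode each
#' node searches its neighbours only within the opposite part, and no two
#' nodes of the same part share an edge — the connectivity rule of
#' two-barcode-species chemistries.
#'
#' @param points coordinate matrix (rows = nodes).
#' @param k neighbours per node; the field's defaults are 6 in 2D and 15 in
#'   3D (mean Voronoi neighbour counts).
#' @param bipartite build a bipartite KNN graph.
#' @param parts optional part labels (`"A"`/`"B"`); when `bipartite = TRUE`
#'   and `parts` is `NULL`, a seeded random 50/50 split is drawn.
#' @param seed seed for the default part split.
#' @return A [spatial_graph] with `positions` attached (and `parts` in
#'   bipartite mode).
#' @export
knn_graph <- function(points, k = 6L, bipartite = FALSE, parts = NULL,
                      seed = 1L) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (bipartite && is.null(parts)) {
    set.seed(seed)
    parts <- sample(rep(c("A", "B"), length.out = n))
  }
  if (!bipartite) parts <- NULL
  dm <- as.matrix(stats::dist(points))
  diag(dm) <- Inf
  if (bipartite) {
    same <- outer(parts, parts, "==")
    dm[same] <- Inf
  }
  cand <- min(apply(is.finite(dm), 1L, sum))
  if (k >= cand + ifelse(bipartite, 1L, 1L) && k > cand) {
    stop(sprintf("k = %d exceeds the available candidate neighbours (%d)", k, cand))
  }
  nb <- t(apply(dm, 1L, function(row) order(row)[seq_len(k)]))
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nb)))
  edges <- unique_undirected(edges, n)
  spatial_graph(edges, n = n, positions = points, parts = parts)
}

# drop duplicate undirected pairs, keep canonical order
unique_undirected <- function(edges, n) {
  flip <- edges[, 1L] > edges[, 2L]
  edges[flip, ] <- edges[flip, 2:1]
  key <- (edges[, 1L] - 1) * as.double(n) + edges[, 2L]
  edges[!duplicated(key), , drop = FALSE]
}

#' Diffusion-decay random connectivity
#'
#' Links every node pair independently with probability
#' \eqn{p_{ij} = \exp(-d_{ij}^2 / L_{diff}^2)}: the probability that two
#' polonies a distance \eqn{d_{ij}} apart interact within a diffusion length
#' \eqn{L_{diff}}.
#'
#' @param points coordinate matrix.
#' @param l_diff diffusion length (same units as the coordinates).
#' @param seed seed for the Bernoulli draws.
#' @return A [spatial_graph] with positions attached. May be disconnected
#'   for small `l_diff`; metrics then operate on the largest component.
#' @export
diffusion_graph <- function(points, l_diff, seed = 1L) {
  if (l_diff <= 0) stop("'l_diff' must be positive")
  points <- as.matrix(points)
  n <- nrow(points)
  dm <- as.matrix(stats::dist(points))
  idx <- which(upper.tri(dm))
  p <- exp(-(dm[idx] / l_diff)^2)
  set.seed(seed)
  hit <- stats::runif(length(idx)) < p
  edges <- cbind(row(dm)[idx][hit], col(dm)[idx][hit])
  spatial_graph(edges, n = n, positions = points)
}

#' Swiss-roll benchmark networks
#'
#' Points on a rolled 2D strip embedded in 3D — parameter \eqn{t} on
#' \eqn{[1.5\pi, 4.5\pi]} (sampled uniformly by arc length), embedding
#' \eqn{(t\cos t,\; h,\; t\sin t)} with height \eqn{h} uniform — with three
#' edge regimes:
#' \describe{
#'   \item{`"SR"`}{proximity-only: ambient-distance KNN, with the strip
#'     height chosen so the inter-layer gap (\eqn{2\pi}) is about three
#'     median KNN edge lengths and KNN edges stay on the manifold;}
#'   \item{`"ISR"`}{SR plus short inter-layer bridges: for a fraction
#'     `bridge_frac` of nodes, one edge to the ambient-nearest node of an
#'     adjacent winding (a point whose along-strip geodesic distance exceeds
#'     3x the ambient distance);}
#'   \item{`"NSR"`}{SR plus uniformly random false edges totalling
#'     `noise_ratio` of the SR edge count.}
#' }
#'
#' @param n number of points (default 3000).
#' @param k KNN parameter for the proximity edges (default 6: the strip is a
#'   2D manifold).
#' @param variant `"SR"`, `"ISR"` or `"NSR"`.
#' @param noise_ratio false-edge ratio for NSR (default 0.10), in `[0, 1)`.
#' @param bridge_frac fraction of nodes receiving an inter-layer bridge in
#'   ISR (default 0.05).
#' @param height strip height; `NULL` (default) picks the height that makes
#'   the expected median KNN edge length about one third of the inter-layer
#'   gap.
#' @param seed integer seed.
#' @return A [spatial_graph] with 3D `positions`; attribute `"manifold"`
#'   holds the unrolled (arc length, height) coordinates and attribute
#'   `"sr_edges"` the proximity-only edge count.
#' @export
swiss_roll <- function(n = 3000L, k = 6L, variant = c("SR", "ISR", "NSR"),
                       noise_ratio = 0.10, bridge_frac = 0.05,
                       height = NULL, seed = 1L) {
  variant <- match.arg(variant)
  if (variant == "NSR" && (noise_ratio < 0 || noise_ratio >= 1)) {
    stop("'noise_ratio' must lie in [0, 1)")
  }
  t0 <- 1.5 * pi; t1 <- 4.5 * pi
  # cumulative arc length s(t) = int sqrt(1 + t^2) dt, for uniform-by-area sampling
  tg <- seq(t0, t1, length.out = 2048L)
  sg <- cumsum(c(0, diff(tg) * sqrt(1 + ((tg[-1] + tg[-length(tg)]) / 2)^2)))
  arc_len <- sg[length(sg)]
  if (is.null(height)) {
    # density at which the ~4th-neighbour distance equals gap/3 = 2*pi/3
    rho <- 4 / (pi * (2 * pi / 3)^2)
    height <- n / (arc_len * rho)
  }
  set.seed(seed)
  s <- stats::runif(n, 0, arc_len)
  tpar <- stats::approx(sg, tg, xout = s)$y
  h <- stats::runif(n, 0, height)
  pos <- cbind(x = tpar * cos(tpar), y = h, z = tpar * sin(tpar))

  g <- knn_graph(pos, k = k)
  attr(g, "manifold") <- cbind(s = s, h = h)
  attr(g, "sr_edges") <- nrow(g$edges)

  if (variant == "ISR") {
    n_bridge <- max(1L, round(bridge_frac * n))
    picks <- sample.int(n, n_bridge)
    new_edges <- matrix(integer(), ncol = 2L)
    for (i in picks) {
      amb <- sqrt(colSums((t(pos) - pos[i, ])^2))
      geo <- sqrt((s - s[i])^2 + (h - h[i])^2)
      ok <- geo > 3 * amb & seq_len(n) != i
      if (!any(ok)) next
      j <- which(ok)[which.min(amb[ok])]
      new_edges <- rbind(new_edges, c(i, j))
    }
    edges <- unique_undirected(rbind(g$edges, new_edges), n)
    g2 <- spatial_graph(edges, n = n, positions = pos)
    attr(g2, "manifold") <- attr(g, "manifold")
    attr(g2, "sr_edges") <- attr(g, "sr_edges")
    g <- g2
  } else if (variant == "NSR") {
    n_false <- round(noise_ratio * nrow(g$edges))
    if (n_false > 0) {
      pert <- add_false_edges(g, n_false, seed = seed + 1L)
      sr_edges <- attr(g, "sr_edges"); manif <- attr(g, "manifold")
      g <- pert$graph
      attr(g, "manifold") <- manif
      attr(g, "sr_edges") <- sr_edges
      attr(g, "perturbation") <- pert$record
    }
  }
  g
}

#' Polony diffusion edge weights
#'
#' Assigns each edge the interaction weight
#' \eqn{w_{ij} = W \exp(-d_{ij}^2 / L_{diff}^2)} of the polony diffusion
#' model, where \eqn{d_{ij}} is the ground-truth distance, `W` the amplitude
#' (reactivity x sequencing depth) and `l_diff` the diffusion length.
#'
#' @param g a [spatial_graph] with positions.
#' @param amplitude amplitude `W` (> 0).
#' @param l_diff diffusion length.
#' @param round_counts round weights to integer counts (minimum 1), as read
#'   counts would be; off by default so that [weight_to_distance()] is an
#'   exact inverse.
#' @return The graph with `weights` attached.
#' @export
polony_weights <- function(g, amplitude = 10, l_diff = 1, round_counts = FALSE) {
  if (is.null(g$positions)) stop("ground-truth positions are required")
  if (amplitude <= 0 || l_diff <= 0) stop("'amplitude' and 'l_diff' must be positive")
  d <- edge_euclidean_lengths(g)
  w <- amplitude * exp(-(d / l_diff)^2)
  if (round_counts) w <- pmax(1, round(w))
  spatial_graph(g$edges, n = g$n, weights = w, positions = g$positions,
                parts = g$parts, ids = g$ids)
}

edge_euclidean_lengths <- function(g) {
  p <- g$positions
  sqrt(rowSums((p[g$edges[, 1L], , drop = FALSE] -
                  p[g$edges[, 2L], , drop = FALSE])^2))
}

#' Invert edge weights to metric distances
#'
#' Inverts the polony diffusion weight model:
#' \eqn{d_{ij} = \sqrt{-\ln(w_{ij}/W)} \cdot L_{diff}}. The amplitude `W`
#' defaults to the peak observed weight, the experimental estimate. A weight
#' equal to `W` maps to distance 0 and is clamped to
#' \eqn{10^{-6} L_{diff}} so that zero-length edges do not collapse the
#' shortest-path metric. Changing `l_diff` rescales all distances by a
#' common factor and leaves their relative distribution unchanged.
#'
#' @param g a weighted [spatial_graph].
#' @param amplitude amplitude `W`; `NULL` uses `max(weights)`.
#' @param l_diff diffusion length scale (default 1).
#' @return The graph with per-edge `lengths` attached, ready for
#'   `shortest_path_matrix(g, mode = "weighted")`.
#' @export
weight_to_distance <- function(g, amplitude = NULL, l_diff = 1) {
  if (is.null(g$weights)) stop("edge weights are required")
  w <- g$weights
  if (is.null(amplitude)) amplitude <- max(w)
  if (any(w > amplitude)) stop("weights exceed the amplitude 'W'")
  d <- sqrt(-log(w / amplitude)) * l_diff
  d <- pmax(d, 1e-6 * l_diff)
  spatial_graph(g$edges, n = g$n, weights = w, lengths = d,
                positions = g$positions, parts = g$parts, ids = g$ids)
}

#' Diffusion length from diffusion constant and time
#'
#' \eqn{L_{diff} = \sqrt{8 D t}}. With the diffusion constant of ~100-nt DNA
#' in dense media (\eqn{\sim 10^{-12}\, m^2/s}) and minutes of diffusion,
#' the characteristic length is of order 10 um.
#'
#' @param d_coeff diffusion constant (m^2/s).
#' @param t diffusion time (s).
#' @return Diffusion length in metres.
#' @examples
#' diffusion_length(1e-12, 60)  # ~2.2e-5 m
#' @export
diffusion_length <- function(d_coeff, t) {
  if (d_coeff <= 0 || t <= 0) stop("'d_coeff' and 't' must be positive")
  sqrt(8 * d_coeff * t)
}

#' Generate a synthetic spatial network
#'
#' One-call generator covering the standard study conditions: uniform points
#' in a disk (2D) or ball (3D) joined by unipartite KNN (K = 6 in 2D, 15 in
#' 3D), bipartite KNN, or diffusion-decay connectivity; optionally weighted
#' by the polony diffusion model.
#'
#' @param n number of points.
#' @param dim physical dimension, 2 or 3.
#' @param mode `"knn"`, `"bipartite_knn"` or `"diffusion"`.
#' @param k KNN parameter; `NULL` uses 6 (2D) or 15 (3D).
#' @param shape region shape; `NULL` uses disk (2D) or sphere (3D).
#' @param l_diff diffusion length for `mode = "diffusion"` and for weights.
#' @param weighted attach polony diffusion weights.
#' @param amplitude weight amplitude `W`.
#' @param seed integer seed.
#' @return A [spatial_graph] with ground-truth positions.
#' @examples
#' g <- generate_network(n = 500, seed = 42)
#' summary(g)
#' @export
generate_network <- function(n = 3000L, dim = 2L,
                             mode = c("knn", "bipartite_knn", "diffusion"),
                             k = NULL, shape = NULL, l_diff = 0.1,
                             weighted = FALSE, amplitude = 10, seed = 1L) {
  mode <- match.arg(mode)
  if (!dim %in% c(2L, 3L)) stop("'dim' must be 2 or 3")
  if (is.null(shape)) shape <- if (dim == 2L) "disk" else "sphere"
  if (is.null(k)) k <- if (dim == 2L) 6L else 15L
  pts <- sample_points(n, shape = shape, seed = seed)
  g <- switch(mode,
    knn = knn_graph(pts, k = k),
    bipartite_knn = knn_graph(pts, k = k, bipartite = TRUE, seed = seed + 1L),
    diffusion = diffusion_graph(pts, l_diff = l_diff, seed = seed + 1L)
  )
  if (weighted) g <- polony_weights(g, amplitude = amplitude, l_diff = l_diff)
  g
}
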