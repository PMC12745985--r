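test_that("point sampling respects regions and seeds", {
  d <- sample_points(500, "disk", seed = 3)
  expect_true(all(rowSums(d^2) <= 1))
  s <- sample_points(500, "sphere", seed = 3)
  expect_equal(ncol(s), 3)
  expect_true(all(rowSums(s^2) <= 1))
  q <- sample_points(200, "square", seed = 3)
  expect_true(all(q >= 0 & q <= 1))
  expect_identical(sample_points(100, "disk", seed = 9),
                   sample_points(100, "disk", seed = 9))
})

test_that("KNN graphs are union-symmetrised and bipartite mode stays bipartite", {
  pts <- cbind(c(0, 1, 3), 0)
  g <- knn_graph(pts, k = 1)
  expect_equal(g$edges, rbind(c(1L, 2L), c(2L, 3L)))

  g6 <- generate_network(n = 300, k = 6, seed = 2)
  expect_true(all(spatialcoherence:::node_degrees(g6) >= 6))

  bp <- generate_network(n = 300, mode = "bipartite_knn", k = 6, seed = 2)
  expect_false(is.null(bp$parts))
  expect_true(all(bp$parts[bp$edges[, 1]] != bp$parts[bp$edges[, 2]]))
  expect_true(all(spatialcoherence:::node_degrees(bp) >= 6))
})

test_that("diffusion connectivity matches its Bernoulli expectation", {
  pts <- sample_points(40, "disk", seed = 6)
  dm <- as.matrix(dist(pts))
  p <- exp(-(dm[upper.tri(dm)] / 0.5)^2)
  counts <- sapply(1:100, function(s) nrow(diffusion_graph(pts, 0.5, seed = s)$edges))
  se <- sqrt(sum(p * (1 - p)) / 100)
  expect_lt(abs(mean(counts) - sum(p)), 3 * se + 1e-9)
})

test_that("swiss-roll variants have the prescribed edge structure", {
  sr <- swiss_roll(n = 800, variant = "SR", seed = 4)
  isr <- swiss_roll(n = 800, variant = "ISR", seed = 4)
  nsr <- swiss_roll(n = 800, variant = "NSR", noise_ratio = 0.1, seed = 4)
  m <- attr(sr, "sr_edges")
  expect_gt(nrow(isr$edges), nrow(sr$edges))
  expect_equal(nrow(nsr$edges), m + round(0.1 * m))
  expect_error(swiss_roll(n = 100, variant = "NSR", noise_ratio = 1), "noise_ratio")
  # ground truth always attached
  expect_equal(ncol(sr$positions), 3)
})

test_that("polony weights follow the diffusion decay and invert exactly", {
  pts <- rbind(c(0, 0), c(0, 0), c(1, 0), c(2.5, 0))
  g <- spatial_graph(rbind(c(1, 2), c(1, 3), c(1, 4)), positions = pts)
  w <- polony_weights(g, amplitude = 10, l_diff = 1)
  expect_equal(w$weights[1], 10)          # d = 0 -> W
  expect_equal(w$weights[2], 10 * exp(-1))  # d = l_diff -> W/e
  expect_true(all(diff(w$weights) < 0))   # decreasing in distance

  net <- generate_network(n = 150, k = 4, seed = 12, weighted = TRUE,
                          l_diff = 0.3)
  inv <- weight_to_distance(net, amplitude = 10, l_diff = 0.3)
  expect_equal(inv$lengths, spatialcoherence:::edge_euclidean_lengths(net),
               tolerance = 1e-12)

  # w = W maps to zero, clamped to epsilon for the path metric
  expect_equal(weight_to_distance(w, amplitude = 10, l_diff = 1)$lengths[1],
               1e-6)
  expect_error(weight_to_distance(w, amplitude = 5), "exceed")
})

test_that("weight-to-distance ranking is invariant to the length scale", {
  net <- generate_network(n = 100, k = 4, seed = 13, weighted = TRUE,
                          l_diff = 0.4)
  a <- weight_to_distance(net, l_diff = 1)$lengths
  b <- weight_to_distance(net, l_diff = 7)$lengths
  expect_equal(cor(a, b, method = "spearman"), 1)
  expect_equal(b / a, rep(7, length(a)), tolerance = 1e-9)
})

test_that("diffusion length follows sqrt(8 D t)", {
  expect_equal(diffusion_length(1 / 8, 1), 1)
  expect_equal(diffusion_length(4e-12, 60), 2 * diffusion_length(1e-12, 60))
  expect_equal(diffusion_length(1e-12, 60), sqrt(8 * 1e-12 * 60))
  expect_error(diffusion_length(-1, 1), "positive")
})
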