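test_that("shortest-path matrix matches hand examples and has metric shape", {
  path3 <- spatial_graph(rbind(c(1, 2), c(2, 3)))
  d <- shortest_path_matrix(path3)
  expect_equal(d[1, 3], 2)
  expect_equal(diag(d), rep(0, 3))
  expect_equal(d, t(d))

  disc <- spatial_graph(rbind(c(1, 2), c(3, 4)), n = 4)
  expect_error(shortest_path_matrix(disc), "2 components")
  expect_error(shortest_path_matrix(path3, mode = "weighted"), "lengths")
})

test_that("shortest-path matrix agrees with Floyd-Warshall on random graphs", {
  for (seed in 1:3) {
    g <- random_connected_graph(20, p = 0.2, seed = seed)
    d <- shortest_path_matrix(g)
    expect_equal(unclass(d), fw_spdm(g$edges, g$n), ignore_attr = TRUE)
    # triangle inequality of the hop metric
    for (k in sample(20, 5)) {
      expect_true(all(d <= outer(d[, k], d[k, ], "+") + 1e-12))
    }
  }
})

test_that("bfs_ball counts and nesting behave", {
  ring <- ring_graph(10)
  expect_length(bfs_ball(ring, 1, 2), 5)
  star <- spatial_graph(cbind(1, 2:8))
  expect_length(bfs_ball(star, 1, 1), 8)
  # saturation at eccentricity
  expect_length(bfs_ball(ring, 1, 5), 10)
  expect_error(bfs_ball(ring, 1, -1), "nonnegative")
  g <- random_connected_graph(15, p = 0.2, seed = 4)
  for (d in 1:4) {
    expect_true(all(bfs_ball(g, 3, d) %in% bfs_ball(g, 3, d + 1)))
  }
})

test_that("ball growth follows closed forms on rings and lattices", {
  ring <- ring_graph(1000)
  bg <- ball_growth(ring, 17, max_depth = 100)
  expect_equal(bg$nodes, 2 * bg$depth + 1)

  lat <- lattice_graph(41)
  center <- (41^2 + 1) / 2
  bg <- ball_growth(lat, center, max_depth = 15)  # von Neumann ball
  expect_equal(bg$nodes, 2 * bg$depth^2 + 2 * bg$depth + 1)

  g <- random_connected_graph(25, p = 0.15, seed = 9)
  expect_true(all(diff(ball_growth(g, 1)$nodes) >= 0))
  # counts include the origin: depth-1 ball is the closed neighbourhood
  expect_equal(ball_growth(g, 1)$nodes[1],
               sum(g$edges == 1) + 1)
})

test_that("closeness centrality matches hand sums and is label-invariant", {
  path5 <- spatial_graph(cbind(1:4, 2:5))
  expect_equal(closeness_centrality(path5)[3], 1 / 6)
  k5 <- spatial_graph(t(combn(5, 2)))
  expect_equal(closeness_centrality(k5), rep(1 / 4, 5))

  g <- random_connected_graph(30, p = 0.15, seed = 2)
  cc <- closeness_centrality(g)
  expect_equal(cc, 1 / rowSums(fw_spdm(g$edges, g$n)))
  # permutation invariance
  set.seed(1)
  perm <- sample(30)
  gp <- spatial_graph(matrix(perm[g$edges], ncol = 2), n = 30)
  expect_equal(closeness_centrality(gp)[perm], cc)
})

test_that("central origin selection clamps between hard min and soft max", {
  expect_length(select_central_origins(ring_graph(500)), 10)   # 1% below min
  expect_length(select_central_origins(ring_graph(2000)), 20)  # plain 1%
  expect_length(select_central_origins(ring_graph(12000)), 100) # capped
  k5 <- spatial_graph(t(combn(5, 2)))
  expect_equal(select_central_origins(k5), 1:5)  # never exceeds N; id ties
})

test_that("BFS-sampled subgraph completes shells and stays connected", {
  ring <- ring_graph(100)
  expect_equal(sample_subgraph(ring, 1, 200)$n, 100L)
  sub <- sample_subgraph(ring, 1, 10)
  expect_gte(sub$n, 10)
  expect_equal(n_components(sub), 1L)

  g <- random_connected_graph(30, p = 0.2, seed = 6)
  sub <- sample_subgraph(g, 5, 12)
  expect_equal(n_components(sub), 1L)
  # induced edges equal brute-force filtering of the original edge list
  nodes <- attr(sub, "mapping")
  manual <- g$edges[g$edges[, 1] %in% nodes & g$edges[, 2] %in% nodes, ,
                    drop = FALSE]
  relab <- match(as.vector(manual), nodes)
  manual <- matrix(relab, ncol = 2)
  manual <- manual[order(pmin(manual[, 1], manual[, 2]),
                         pmax(manual[, 1], manual[, 2])), ]
  expect_equal(sub$edges,
               matrix(as.integer(manual), ncol = 2), ignore_attr = TRUE)
})
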