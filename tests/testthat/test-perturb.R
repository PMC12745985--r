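test_that("false-edge insertion does exact bookkeeping", {
  g <- generate_network(n = 200, k = 4, seed = 3)
  m <- nrow(g$edges)
  p <- add_false_edges(g, 0.1, seed = 7)
  expect_equal(nrow(p$graph$edges), m + round(0.1 * m))
  expect_equal(p$record$false_ratio, round(0.1 * m) / m)
  # added edges were absent from the original
  orig <- spatialcoherence:::edge_key(g$edges, g$n)
  added <- spatialcoherence:::edge_key(p$record$added_edges, g$n)
  expect_length(intersect(orig, added), 0)

  # removing exactly the added edges restores the original graph
  keys <- spatialcoherence:::edge_key(p$graph$edges, g$n)
  restored <- p$graph$edges[!(keys %in% added), ]
  expect_equal(restored, g$edges)

  expect_error(add_false_edges(spatial_graph(t(combn(5, 2))), 3), "non-adjacent")
})

test_that("false edges can be length-biased and respect bipartiteness", {
  g <- generate_network(n = 200, k = 4, seed = 3)
  p <- add_false_edges(g, 20, min_length = 0.8, seed = 1)
  lens <- spatialcoherence:::edge_euclidean_lengths(
    spatial_graph(p$record$added_edges, n = g$n, positions = g$positions))
  expect_true(all(lens >= 0.8))

  bp <- generate_network(n = 200, mode = "bipartite_knn", seed = 4)
  pb <- add_false_edges(bp, 30, seed = 2)
  a <- pb$record$added_edges
  expect_true(all(bp$parts[a[, 1]] != bp$parts[a[, 2]]))
})

test_that("edge removal hits the ratio and preserves connectivity", {
  g <- generate_network(n = 400, k = 6, seed = 5)
  m <- nrow(g$edges)
  expect_equal(remove_edges(g, 0, seed = 1)$graph$edges, g$edges)
  r <- remove_edges(g, 0.3, seed = 1)
  expect_equal(nrow(r$graph$edges), m - round(0.3 * m))
  expect_equal(n_components(r$graph), 1L)
  expect_equal(r$record$missing_ratio, round(0.3 * m) / m)
  # a tree admits no removal at all
  tree <- spatial_graph(cbind(1:9, 2:10))
  expect_error(remove_edges(tree, 0.5, seed = 1, max_attempts = 50),
               "disconnecting")
})

test_that("filter evaluation reproduces confusion-matrix arithmetic", {
  g <- ring_graph(20)
  p <- add_false_edges(g, 4, seed = 3)
  rec <- p$record
  false_edges <- rec$added_edges

  perfect <- evaluate_filter(rec, false_edges)
  expect_equal(unname(perfect), c(1, 1, 1))

  nothing <- evaluate_filter(rec, matrix(integer(), ncol = 2))
  expect_equal(unname(nothing["recall"]), 0)
  expect_equal(unname(nothing["f1"]), 0)

  # 3 of 4 false edges plus 1 true edge removed
  mixed <- evaluate_filter(rec, rbind(false_edges[1:3, ], g$edges[1, ]))
  expect_equal(unname(mixed), c(0.75, 0.75, 0.75))

  expect_error(evaluate_filter(rec, rbind(c(5, 99))), "outside")
})
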