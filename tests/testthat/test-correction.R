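test_that("weight ranking sorts descending with deterministic ties", {
  g <- spatial_graph(rbind(c(1, 2), c(2, 3), c(3, 4)), weights = c(3, 1, 2))
  rk <- score_by_weight(g)
  expect_equal(rk$scores, c(3, 2, 1))
  expect_equal(rk$edges[1, ], c(1L, 2L))
  expect_warning(score_by_weight(spatial_graph(rbind(c(1, 2), c(2, 3)),
                                               weights = c(2, 2))),
                 "no information")
  # top-k against a brute-force sort
  net <- generate_network(n = 80, k = 4, seed = 6, weighted = TRUE, l_diff = 0.5)
  rk <- score_by_weight(net)
  expect_equal(rk$scores, sort(net$weights, decreasing = TRUE))
})

test_that("indirect-path scores match hand-enumerated cases", {
  sq <- spatial_graph(rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4)))
  rk <- score_by_indirect_paths(sq, L = 3)
  expect_equal(rk$scores, rep(1, 4))  # each edge has one 3-step detour

  k4 <- spatial_graph(t(combn(4, 2)))
  expect_equal(score_by_indirect_paths(k4, L = 3)$scores, rep(2, 6))

  # bridge between two triangles has no detour at all
  bridge <- spatial_graph(rbind(c(1, 2), c(2, 3), c(1, 3),
                                c(3, 4),
                                c(4, 5), c(5, 6), c(4, 6)))
  rk <- score_by_indirect_paths(bridge, L = 3)
  i <- which(rk$edges[, 1] == 3 & rk$edges[, 2] == 4)
  expect_equal(rk$scores[i], 0)
})

test_that("indirect-path scores agree with exhaustive enumeration", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(4:8, 1)
    g <- random_connected_graph(n, p = 0.45, seed = seed + 20)
    for (L in c(2L, 3L, 4L)) {
      rk <- score_by_indirect_paths(g, L = L)
      for (r in seq_len(nrow(rk$edges))) {
        expect_equal(
          rk$scores[r],
          enum_indirect_paths(g$edges, n, rk$edges[r, 1], rk$edges[r, 2], L),
          info = sprintf("seed %d L %d edge %d-%d", seed, L,
                         rk$edges[r, 1], rk$edges[r, 2]))
      }
    }
  }
})

test_that("filter_graph keeps the rounded top fraction and nests", {
  net <- generate_network(n = 60, k = 4, seed = 2, weighted = TRUE, l_diff = 0.5)
  rk <- score_by_weight(net)
  m <- nrow(net$edges)
  expect_equal(nrow(filter_graph(net, rk, 1)$edges), m)
  expect_equal(nrow(filter_graph(net, rk, 0)$edges), 0)
  expect_equal(nrow(filter_graph(net, rk, 0.5)$edges), floor(0.5 * m + 0.5))
  taus <- c(0.2, 0.4, 0.7, 0.9)
  keys <- lapply(taus, function(tau)
    spatialcoherence:::edge_key(filter_graph(net, rk, tau)$edges, net$n))
  for (i in 1:3) expect_true(all(keys[[i]] %in% keys[[i + 1]]))
  # retained edges carry their original weights
  f <- filter_graph(net, rk, 0.5)
  expect_equal(sort(f$weights, decreasing = TRUE),
               rk$scores[seq_len(nrow(f$edges))])
})

test_that("golden-section search matches a dense grid on unimodal objectives", {
  fns <- list(function(x) -(x - 0.6)^2,
              function(x) -abs(x - 0.13),
              function(x) dnorm(x, 0.85, 0.2))
  grid <- seq(0, 1, by = 0.005)
  for (f in fns) {
    gs <- golden_section_max(f, 0, 1, tol = 0.01, max_iter = 50)
    expect_equal(gs$x, grid[which.max(sapply(grid, f))], tolerance = 0.01)
    expect_lte(nrow(gs$trace), 52)  # initial two points + one per iteration
  }
  # the same oracle through the optimize_filter test seam
  net <- generate_network(n = 40, k = 3, seed = 1)
  rk <- score_by_indirect_paths(net)
  fr <- optimize_filter(net, rk, objective = function(tau) -(tau - 0.6)^2)
  expect_equal(fr$tau_star, 0.6, tolerance = 0.01)
})

test_that("a perfect ranking lets the filter remove injected false edges", {
  g <- generate_network(n = 300, k = 6, seed = 10)
  p <- add_false_edges(g, 0.15, seed = 11)
  noisy <- p$graph
  false_keys <- spatialcoherence:::edge_key(p$record$added_edges, noisy$n)
  keys <- spatialcoherence:::edge_key(noisy$edges, noisy$n)
  # construct an oracle ranking: true edges first, false edges last
  ord <- order(keys %in% false_keys)
  ranking <- structure(list(edges = noisy$edges[ord, ],
                            scores = rev(seq_along(ord)),
                            method = "oracle"),
                       class = "edge_ranking")
  fr <- optimize_filter(noisy, ranking, dim = 2)
  expect_gte(fr$delta_s, 0)
  scores <- evaluate_filter(p$record, fr$removed)
  expect_gt(scores["recall"], 0.5)
})
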