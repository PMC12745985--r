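test_that("double centering reproduces hand-computed Gram matrices", {
  g <- gram_from_distances(rbind(c(0, 2), c(2, 0)))
  expect_equal(g, rbind(c(1, -1), c(-1, 1)))
  expect_equal(eigen(g, symmetric = TRUE)$values, c(2, 0))

  # unit-square corners: centred Gram has nonzero eigenvalues {1, 1}
  pts <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  ev <- eigen(gram_from_distances(as.matrix(dist(pts))),
              symmetric = TRUE)$values
  expect_equal(ev, c(1, 1, 0, 0), tolerance = 1e-12)

  expect_equal(gram_from_distances(matrix(0, 3, 3)), matrix(0, 3, 3))
  # double centering: rows sum to zero
  d <- shortest_path_matrix(random_connected_graph(15, p = 0.2, seed = 3))
  expect_equal(rowSums(gram_from_distances(d)), rep(0, 15), tolerance = 1e-10)
})

test_that("spectral scores follow the eigenvalue arithmetic", {
  s <- spectral_scores(c(3, 1, 0, 0), dim = 2)
  expect_equal(s$variance_contribution, 1)
  expect_equal(s$spectral_gap, 1)

  s <- spectral_scores(c(2, 1, 1, 0), dim = 2)
  expect_equal(s$variance_contribution, 0.75)
  expect_equal(s$spectral_gap, 0)

  # denominator conventions on a spectrum with a negative tail
  ev <- c(4, 2, 1, -1)
  expect_equal(spectral_scores(ev, 2, "all")$variance_contribution, 1)
  expect_equal(spectral_scores(ev, 2, "positive")$variance_contribution, 6 / 7)
  expect_equal(spectral_scores(ev, 2, "abs")$variance_contribution, 6 / 8)

  # lambda_D <= 0: gap flagged undefined rather than silently computed
  s <- spectral_scores(c(1, 0, -0.5), dim = 2)
  expect_false(s$gap_defined)
  expect_true(is.na(s$spectral_gap))
})

test_that("exact Euclidean distances give C_D = 1 and gap = 1", {
  for (D in 1:3) {
    set.seed(D)
    pts <- matrix(runif(200 * D), ncol = D)
    s <- spectral_scores(gram_from_distances(as.matrix(dist(pts))), dim = D)
    expect_equal(s$variance_contribution, 1, tolerance = 1e-9)
    expect_equal(s$spectral_gap, 1, tolerance = 1e-9)
    # at most D eigenvalues are numerically positive
    ev <- s$eigenvalues
    expect_lt(abs(ev[D + 1]) / ev[1], 1e-9)
  }
})

test_that("classical MDS inverts coordinate -> EDM exactly", {
  # two points at distance 2, one dimension: +-1 up to sign
  coords <- reconstruct_classical_mds(
    gram_from_distances(rbind(c(0, 2), c(2, 0))), dim = 1)
  expect_equal(sort(as.numeric(coords)), c(-1, 1))

  set.seed(42)
  pts <- cbind(runif(80), runif(80))
  rec <- reconstruct_classical_mds(gram_from_distances(as.matrix(dist(pts))),
                                   dim = 2)
  expect_equal(colMeans(rec), c(0, 0), tolerance = 1e-10)
  expect_lt(procrustes_rms(pts, rec), 1e-6)
})

test_that("graph spectral scores sample large graphs deterministically", {
  g <- generate_network(n = 400, k = 6, seed = 8)
  full <- graph_spectral_scores(g, dim = 2)
  capped <- graph_spectral_scores(g, dim = 2, node_cap = 200L)
  expect_lte(length(capped$eigenvalues), 400)
  expect_gte(length(capped$eigenvalues), 200)
  # same call twice: identical
  expect_identical(full$eigenvalues,
                   graph_spectral_scores(g, dim = 2)$eigenvalues)
})
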