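test_that("degrees and clustering on canonical graphs", {
  full <- matrix(1L, 5, 5); diag(full) <- 0L
  net <- as_econet_network(full)
  deg <- degree_centrality(net)
  expect_true(all(deg$indegree == 4) && all(deg$outdegree == 4))
  cc <- clustering_coefficient(net)
  expect_true(all(cc$clustering == 1))  # triangle-complete

  empty <- as_econet_network(matrix(0L, 4, 4))
  dem <- degree_centrality(empty)
  expect_true(all(dem$indegree == 0) && all(dem$outdegree == 0))

  # star: centre -> 4 leaves; centre has no triangles, leaves have k = 1
  star <- matrix(0L, 5, 5); star[1, 2:5] <- 1L
  ccs <- clustering_coefficient(as_econet_network(star))
  expect_equal(ccs$clustering, rep(0, 5))

  tri <- matrix(1L, 3, 3); diag(tri) <- 0L
  expect_equal(clustering_coefficient(as_econet_network(tri))$clustering,
               rep(1, 3))
})

test_that("degrees and clustering agree with brute force on random digraphs", {
  withr::with_seed(42, {
    for (rep in 1:100) {
      n <- sample(3:12, 1)
      A <- rand_digraph(n, stats::runif(1, 0.1, 0.8))
      net <- as_econet_network(A)
      oracle <- brute_degrees(A)
      deg <- degree_centrality(net)
      expect_identical(deg$indegree, oracle$indegree)
      expect_identical(deg$outdegree, oracle$outdegree)
      expect_equal(clustering_coefficient(net)$clustering,
                   brute_clustering(A))
    }
  })
})

test_that("eigenvector centrality matches a dense eigendecomposition", {
  withr::with_seed(7, {
    checked <- 0
    while (checked < 50) {
      n <- sample(6:12, 1)
      A <- rand_digraph(n, 0.4)
      if (sum(A) == 0) next
      lam <- eigen(t(A), only.values = TRUE)$values
      if (max(Re(lam)) < 0.5) next  # skip near-acyclic draws
      v <- eigenvector_centrality(as_econet_network(A))$eigenvector
      expect_lt(max(abs(v - dense_eig_centrality(A))), 1e-8)
      expect_true(all(v >= 0 & v <= 1))
      expect_equal(max(v), 1)
      checked <- checked + 1
    }
  })
})

test_that("eigenvector centrality conventions and degenerate cases", {
  full <- matrix(1L, 6, 6); diag(full) <- 0L
  ev <- eigenvector_centrality(as_econet_network(full))
  expect_equal(ev$eigenvector, rep(1, 6))

  # in-link convention: unreferenced nodes score zero
  A <- matrix(0L, 4, 4)
  A[1, 2] <- A[2, 1] <- A[1, 3] <- A[2, 3] <- 1L  # node 4 isolated, 3 sink
  v <- eigenvector_centrality(as_econet_network(A))$eigenvector
  expect_equal(v[4], 0)
  expect_gt(v[3], 0)

  expect_warning(
    ev0 <- eigenvector_centrality(as_econet_network(matrix(0L, 3, 3))),
    "no edges")
  expect_equal(ev0$eigenvector, rep(0, 3))

  # acyclic direction: chain 1 -> 2 -> 3 has spectral radius zero
  chain <- matrix(0L, 3, 3); chain[1, 2] <- chain[2, 3] <- 1L
  expect_warning(
    evc <- eigenvector_centrality(as_econet_network(chain)), "no cycle")
  expect_equal(evc$eigenvector, rep(0, 3))

  # direction flags move the scores to the other side of the edges
  out <- eigenvector_centrality(as_econet_network(chain), direction = "out")
  expect_warning(out <- eigenvector_centrality(as_econet_network(chain),
                                               direction = "out"), "no cycle")
  sym <- eigenvector_centrality(as_econet_network(chain),
                                direction = "symmetrized")
  expect_equal(max(sym$eigenvector), 1)
})

test_that("the best-connected node attains the maximal score of one", {
  sim <- generate_panel(synthetic_config(seed = 3))
  net <- binarize(compute_gravity(sim$panel, year = min(sim$panel$year)))
  m <- node_metrics(net)
  expect_equal(max(m$eigenvector), 1)
  expect_true(all(m$eigenvector >= 0 & m$eigenvector <= 1))
  expect_true(all(m$clustering >= 0 & m$clustering <= 1))
  # indegree-0 nodes score 0 under the in-link convention
  expect_true(all(m$eigenvector[m$indegree == 0] == 0))
})
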