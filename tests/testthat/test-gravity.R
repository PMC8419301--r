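two_unit_panel <- function(d) {
  tibble::tibble(unit_id = c("a", "b"), year = 2018,
                 x_coord = c(0, d), y_coord = 0, gdp = 1, population = 1)
}

test_that("gravity follows the product / inverse-square form", {
  g <- compute_gravity(two_unit_panel(1))
  expect_equal(g$values["a", "b"], 1)
  g2 <- compute_gravity(two_unit_panel(2))
  expect_equal(g2$values["a", "b"], 0.25)
})

test_that("a 4-unit gravity matrix matches direct pairwise evaluation", {
  p <- tibble::tibble(
    unit_id = c("a", "b", "c", "d"), year = 2018,
    x_coord = c(0, 1, 0, 1), y_coord = c(0, 0, 1, 1),
    gdp = c(1, 2, 3, 4), population = c(1, 1, 2, 2)
  )
  g <- compute_gravity(p)
  mass <- p$gdp * p$population
  for (i in 1:4) {
    for (j in 1:4) {
      if (i == j) {
        expect_identical(g$values[i, j], 0)
      } else {
        d2 <- (p$x_coord[i] - p$x_coord[j])^2 + (p$y_coord[i] - p$y_coord[j])^2
        expect_equal(g$values[i, j], mass[i] * mass[j] / d2)
      }
    }
  }
  expect_identical(g$values, t(g$values))
})

test_that("coincident units are rejected naming the pair", {
  p <- tibble::tibble(unit_id = c("a", "b"), year = 2018,
                      x_coord = 0, y_coord = 0, gdp = 1, population = 1)
  expect_error(compute_gravity(p), "a.*b")
})

test_that("sqrt-mass variant and supplied distance matrices work", {
  p <- two_unit_panel(2)
  p$gdp <- c(4, 9)
  g <- compute_gravity(p, sqrt_masses = TRUE)
  expect_equal(g$values["a", "b"], sqrt(4) * sqrt(9) / 4)
  D <- matrix(c(0, 10, 10, 0), 2)
  gd <- compute_gravity(p, distances = D)
  expect_equal(gd$values["a", "b"], 4 * 9 / 100)
})

test_that("row-mean thresholding uses strict inequality over off-diagonal entries", {
  # constant off-diagonal row: nothing strictly exceeds its mean
  R <- matrix(5, 3, 3); diag(R) <- 0
  g <- structure(list(year = 2018, labels = c("a", "b", "c"), values = R),
                 class = "gravity_matrix")
  net <- binarize(g)
  expect_true(all(net$adjacency == 0))
  # enumerated rows against their own means
  R2 <- matrix(c(0, 10, 2,
                 10, 0, 2,
                 2, 2, 0), 3, byrow = TRUE)
  g2 <- structure(list(year = 2018, labels = c("a", "b", "c"), values = R2),
                  class = "gravity_matrix")
  A <- binarize(g2)$adjacency
  for (i in 1:3) {
    thr <- mean(R2[i, -i])
    for (j in 1:3) {
      expect_identical(A[i, j], as.integer(i != j && R2[i, j] > thr))
    }
  }
  # digraph identity on the result
  expect_equal(sum(colSums(A)), sum(rowSums(A)))
})

test_that("rescaling all gdp by a common factor leaves the network unchanged", {
  sim <- generate_panel(synthetic_config(n_units = 12, n_years = 2, seed = 9))
  p <- dplyr::filter(sim$panel, year == min(year))
  net1 <- binarize(compute_gravity(p))
  p2 <- dplyr::mutate(p, gdp = gdp * 7.3)
  g1 <- compute_gravity(p)
  g2 <- compute_gravity(p2)
  expect_equal(g2$values, g1$values * 7.3^2)
  net2 <- binarize(compute_gravity(p2))
  expect_identical(net1$adjacency, net2$adjacency)
})

test_that("permuting unit order permutes both matrices consistently", {
  sim <- generate_panel(synthetic_config(n_units = 8, n_years = 2, seed = 11))
  p <- dplyr::filter(sim$panel, year == min(year))
  g <- compute_gravity(p)
  net <- binarize(g)
  shuffled <- p[sample(nrow(p)), ]
  g2 <- compute_gravity(shuffled)  # unit order is canonicalized by label
  expect_identical(g2$values, g$values)
  expect_identical(binarize(g2)$adjacency, net$adjacency)
})

test_that("density counts ordered pairs", {
  empty <- as_econet_network(matrix(0L, 4, 4))
  expect_equal(network_density(empty), 0)
  full <- matrix(1L, 5, 5); diag(full) <- 0L
  expect_equal(network_density(as_econet_network(full)), 1)
  withr::with_seed(1, {
    A <- matrix(0L, 31, 31)
    pairs <- which(row(A) != col(A))
    A[sample(pairs, 242)] <- 1L
  })
  expect_equal(sum(A), 242)
  expect_equal(network_density(as_econet_network(A)), 242 / 930)
})

test_that("network exports write the declared formats", {
  sim <- generate_panel(synthetic_config(n_units = 6, n_years = 2, seed = 2))
  g <- compute_gravity(sim$panel, year = min(sim$panel$year))
  net <- binarize(g)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  f3 <- withr::local_tempfile(fileext = ".graphml")
  write_gravity_csv(g, f1)
  gm <- readr::read_csv(f1, show_col_types = FALSE)
  expect_equal(dim(gm), c(6, 7))
  write_edgelist(net, f2)
  edges <- readr::read_csv(f2, show_col_types = FALSE)
  expect_equal(nrow(edges), sum(net$adjacency))
  expect_named(edges, c("source", "target"))
  write_graphml(net, f3)
  reread <- igraph::read_graph(f3, format = "graphml")
  expect_equal(igraph::ecount(reread), sum(net$adjacency))
})
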