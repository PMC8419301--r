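test_that("per-unit summary averages the analysis variables", {
  ap <- tibble::tibble(
    unit_id = rep(c("a", "b"), each = 2), year = rep(2014:2015, 2),
    tfpch = c(1, 2, 3, 5), indegree = c(0, 2, 4, 4),
    eigenvector = c(0, 0, 1, 1), clustering = c(0.2, 0.4, 0.6, 0.6)
  )
  us <- unit_summary(ap)
  expect_equal(us$tfpch, c(1.5, 4))
  expect_equal(us$indegree, c(1, 4))
})

test_that("PCA on rank-1 data concentrates all variance in one component", {
  base <- seq_len(10)
  df <- tibble::tibble(unit_id = sprintf("U%d", 1:10),
                       a = base, b = 2 * base, c = -base, d = 0.5 * base + 3)
  pca <- pca_features(df)
  expect_equal(pca$explained$ratio[1], 1, tolerance = 1e-12)
  expect_equal(pca$explained$ratio[2], 0, tolerance = 1e-12)
})

test_that("independent variables approach isotropy", {
  withr::with_seed(4, {
    df <- tibble::as_tibble(matrix(rnorm(4000 * 4), 4000, 4,
                                   dimnames = list(NULL, letters[1:4])))
  })
  pca <- pca_features(df)
  expect_true(all(abs(pca$explained$ratio - 0.25) < 0.04))
})

test_that("explained variance follows the eigenvalues of the covariance", {
  # build data whose sample covariance has eigenvalues (2.4, 1.0, 0.4, 0.2)
  lambda <- c(2.4, 1.0, 0.4, 0.2)
  withr::with_seed(12, {
    n <- 60
    Z <- matrix(rnorm(n * 4), n, 4)
    Z <- scale(Z, center = TRUE, scale = FALSE)
    W <- Z %*% solve(chol(stats::cov(Z)))      # unit sample covariance
    Q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))     # random rotation
    X <- W %*% diag(sqrt(lambda)) %*% t(Q)     # sample cov = Q diag(l) Q'
  })
  df <- tibble::as_tibble(as.data.frame(X))
  pca <- pca_features(df, standardize = FALSE)
  expect_equal(sort(pca$sdev^2, decreasing = TRUE), sort(lambda, TRUE),
               tolerance = 1e-9)
  expect_equal(pca$explained$cumulative[2], (2.4 + 1.0) / 4,
               tolerance = 1e-9)
})

test_that("full reconstruction and invariants of the decomposition", {
  sim <- generate_panel(synthetic_config(seed = 6))
  us <- unit_summary(analysis_panel(sim$panel))
  pca <- pca_features(us)
  expect_true(all(pca$explained$ratio >= 0 & pca$explained$ratio <= 1))
  expect_true(all(diff(pca$explained$ratio) <= 1e-12))
  expect_equal(sum(pca$explained$ratio), 1, tolerance = 1e-12)
  # reconstruct the standardized data from all components
  Xstd <- scale(as.matrix(us[, pca$vars]))
  recon <- pca$scores_full %*% t(pca$rotation)
  expect_lt(max(abs(recon - Xstd)), 1e-10)
  # sign convention: each component's largest-magnitude loading is positive
  for (j in seq_len(ncol(pca$rotation))) {
    load <- pca$rotation[, j]
    expect_gt(load[which.max(abs(load))], 0)
  }
})

test_that("zero-variance variables are rejected by name", {
  df <- tibble::tibble(a = 1:5, b = rep(2, 5), c = rnorm(5), d = rnorm(5))
  expect_error(pca_features(df), "b")
})

test_that("three point-masses are grouped exactly", {
  scores <- tibble::tibble(
    unit_id = sprintf("U%02d", 1:12),
    PC1 = rep(c(0, 10, 20), each = 4),
    PC2 = rep(c(0, 5, 0), each = 4)
  )
  cl <- select_k_and_cluster(scores, k_range = 2:8, seed = 1)
  expect_equal(cl$chosen_k, 3)
  best <- cl$diagnostics[cl$diagnostics$k == 3, ]
  expect_gt(best$silhouette, 0.99)
  expect_equal(best$inertia, 0, tolerance = 1e-10)
  expect_equal(unname(table(cl$labels$cluster)), rep(4L, 3),
               ignore_attr = TRUE)
})

test_that("inertia is monotone non-increasing in k", {
  sim <- generate_panel(synthetic_config(seed = 10))
  cl <- suppressWarnings(
    select_k_and_cluster(pca_features(unit_summary(analysis_panel(sim$panel))),
                         seed = 2))
  inertia <- cl$diagnostics$inertia[!is.na(cl$diagnostics$inertia)]
  expect_true(all(diff(inertia) <= 1e-8))
})

test_that("a structureless blob yields a low-confidence warning", {
  withr::with_seed(3, {
    scores <- tibble::tibble(PC1 = rnorm(40), PC2 = rnorm(40))
  })
  expect_warning(cl <- select_k_and_cluster(scores, seed = 1), "low-confidence")
  expect_true(cl$chosen_k %in% 2:8)
  expect_true(all(cl$diagnostics$silhouette < 0.5, na.rm = TRUE))
})

test_that("k selection is deterministic and labels stable across seeds", {
  sim <- generate_panel(synthetic_config(seed = 14))
  pca <- pca_features(unit_summary(analysis_panel(sim$panel)))
  a <- select_k_and_cluster(pca, seed = 5)
  b <- select_k_and_cluster(pca, seed = 5)
  expect_identical(a$labels, b$labels)
  expect_identical(a$diagnostics, b$diagnostics)
  sil <- a$diagnostics$silhouette[a$diagnostics$k == a$chosen_k]
  if (sil >= 0.7) {
    for (s in 6:10) {
      other <- select_k_and_cluster(pca, seed = s)
      expect_gte(adj_rand_index(a$labels$cluster, other$labels$cluster), 0.9)
    }
  }
})

test_that("invalid k ranges are rejected", {
  scores <- tibble::tibble(PC1 = rnorm(6), PC2 = rnorm(6))
  expect_error(select_k_and_cluster(scores, k_range = 2:6), "k_range")
  expect_error(select_k_and_cluster(scores, k_range = 1:3), "k_range")
})
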