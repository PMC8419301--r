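# Independent brute-force oracles and fixture builders used across tests.

rand_digraph <- function(n, p) {
  A <- matrix(as.integer(stats::runif(n * n) < p), n, n)
  diag(A) <- 0L
  A
}

# degrees by explicit loops (independent of the matrix-sum implementation)
brute_degrees <- function(A) {
  n <- nrow(A)
  ind <- integer(n); outd <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (A[j, i] == 1L) ind[i] <- ind[i] + 1L
      if (A[i, j] == 1L) outd[i] <- outd[i] + 1L
    }
  }
  list(indegree = ind, outdegree = outd)
}

# clustering coefficient by exhaustive neighbour-pair enumeration
brute_clustering <- function(A) {
  n <- nrow(A)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- integer(0)
    for (j in seq_len(n)) {
      if (j != i && (A[i, j] == 1L || A[j, i] == 1L)) nb <- c(nb, j)
    }
    k <- length(nb)
    if (k < 2) { cc[i] <- 0; next }
    e <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        u <- nb[a]; v <- nb[b]
        if (A[u, v] == 1L || A[v, u] == 1L) e <- e + 1
      }
    }
    cc[i] <- 2 * e / (k * (k - 1))
  }
  cc
}

# dominant eigenvector of the in-link operator from a dense eigendecomposition
dense_eig_centrality <- function(A) {
  ev <- eigen(t(A))
  i <- which.max(Re(ev$values))
  v <- ev$vectors[, i]
  v <- Re(v / v[which.max(abs(v))])
  v <- pmax(v, 0)
  if (max(v) > 0) v <- v / max(v)
  v
}

# closed-form CRS input-oriented efficiency for 1 input / 1 output
ratio_dea <- function(x, y) (y / x) / max(y / x)

geomean <- function(v) exp(mean(log(v)))

# adjusted Rand index between two labelings
adj_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# balanced panel with prescribed DEA inputs/outputs and inert gravity fields
io_panel <- function(X_by_year, Y_by_year, years = NULL) {
  n <- nrow(X_by_year[[1]])
  years <- years %||% (2013 + seq_along(X_by_year) - 1)
  rows <- lapply(seq_along(years), function(ti) {
    X <- X_by_year[[ti]]; Y <- Y_by_year[[ti]]
    tibble::tibble(
      unit_id = sprintf("U%02d", seq_len(n)),
      year = years[ti],
      x_coord = seq_len(n) * 100, y_coord = rep(0, n),
      gdp = 1e6, population = 100,
      institutions = X[, 1], personnel = X[, 2], beds = X[, 3],
      bed_utilization = Y[, 1], outpatient_visits = Y[, 2],
      region = rep(c("west", "east"), length.out = n)
    )
  })
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
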