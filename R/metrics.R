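#' Degree centrality of a directed network
#'
#' Indegree of a node is the number of edges pointing at it (column sum of
#' the binary adjacency); outdegree the number it emits (row sum). In an
#' economic network the indegree proxies a region's agglomeration ability:
#' how many partners are pulled towards it above their own threshold.
#'
#' @param net An `econet_network` (see [binarize()], [as_econet_network()]).
#' @return A tibble: `unit_id`, `year`, `indegree`, `outdegree`.
#' @export
degree_centrality <- function(net) {
  stopifnot(inherits(net, "econet_network"))
  A <- net$adjacency
  tibble(unit_id = net$labels, year = net$year,
         indegree = as.integer(colSums(A)),
         outdegree = as.integer(rowSums(A)))
}

#' Clustering coefficient
#'
#' Fraction of realized edges among each node's neighbours,
#' \eqn{2 E_i / (k_i (k_i - 1))}, computed on the symmetrized graph
#' (`i ~ j` iff an edge runs in either direction): `k_i` is the number of
#' neighbours and `E_i` the number of symmetrized edges among them. Nodes
#' with fewer than two neighbours get 0.
#'
#' @inheritParams degree_centrality
#' @return A tibble: `unit_id`, `year`, `clustering` (in `[0, 1]`).
#' @export
clustering_coefficient <- function(net) {
  stopifnot(inherits(net, "econet_network"))
  A <- net$adjacency
  S <- 1L * ((A + t(A)) > 0)
  k <- rowSums(S)
  cc <- vapply(seq_len(nrow(S)), function(i) {
    if (k[i] < 2) return(0)
    nb <- which(S[i, ] == 1L)
    e <- sum(S[nb, nb]) / 2
    2 * e / (k[i] * (k[i] - 1))
  }, numeric(1))
  tibble(unit_id = net$labels, year = net$year, clustering = cc)
}

#' Eigenvector centrality
#'
#' Principal-eigenvector importance: a node's score is proportional to the
#' summed scores of the nodes linking to it (`direction = "in"`, the
#' default), so the score vector solves \eqn{\lambda v = A^\top v} with
#' \eqn{\lambda} the dominant eigenvalue of the adjacency matrix. Scores are
#' computed by power iteration on the shifted operator `M + I` (the shift
#' leaves eigenvectors untouched while breaking any periodic oscillation)
#' and are max-normalized so the best-connected node scores exactly 1.
#' Nodes with no incoming edges score 0 under the in-link convention.
#'
#' @inheritParams degree_centrality
#' @param direction `"in"` (aggregate over in-links, default), `"out"`, or
#'   `"symmetrized"`.
#' @param tol Relative convergence tolerance of the power iteration.
#' @param max_iter Iteration cap; exceeding it is an error.
#' @return A tibble: `unit_id`, `year`, `eigenvector` (in `[0, 1]`, max 1
#'   whenever the network has at least one edge). A network with no edges,
#'   or one whose aggregation direction carries no cycle (nilpotent
#'   operator, zero spectral radius, so the limiting scores vanish), returns
#'   all zeros with a warning.
#' @export
eigenvector_centrality <- function(net, direction = c("in", "out", "symmetrized"),
                                   tol = 1e-10, max_iter = 1e9) {
  stopifnot(inherits(net, "econet_network"))
  direction <- match.arg(direction)
  A <- net$adjacency
  n <- nrow(A)
  if (sum(A) == 0) {
    warning("network has no edges; eigenvector centrality is all zero")
    return(tibble(unit_id = net$labels, year = net$year,
                  eigenvector = rep(0, n)))
  }
  M <- switch(direction,
              "in" = t(A),
              "out" = A,
              "symmetrized" = 1 * ((A + t(A)) > 0))
  storage.mode(M) <- "double"
  # Zero spectral radius (no cycle in the aggregation direction): M is
  # nilpotent and the limiting scores are identically zero. Exact integer
  # check: M^n annihilates every vector iff M is nilpotent.
  probe <- rep(1, n)
  for (i in seq_len(n)) {
    probe <- as.numeric(M %*% probe)
    if (max(probe) == 0) break
  }
  if (max(probe) == 0) {
    warning("network has no cycle in this direction; eigenvector centrality is all zero")
    return(tibble(unit_id = net$labels, year = net$year,
                  eigenvector = rep(0, n)))
  }
  # Power iteration on the shifted operator M + I (same eigenvectors as M,
  # shift breaks periodicity), accelerated by repeated squaring: k
  # squarings apply 2^k iterations at the cost of k dense products, which
  # rides out the near-tied leading eigenvalues that dense economic blocks
  # produce. Each square is renormalized to its largest entry.
  S <- M + diag(n)
  n_squarings <- max(1L, ceiling(log2(max_iter)))
  for (it in seq_len(n_squarings)) {
    S <- S %*% S
    S <- S / max(S)
  }
  v <- as.numeric(S %*% rep(1, n))
  v <- pmax(v, 0)
  if (max(v) > 0) v <- v / max(v)
  # converged iff v is (numerically) a fixed direction of one more iteration
  w <- as.numeric(M %*% v) + v
  if (max(w) > 0) w <- w / max(w)
  if (max(abs(w - v)) > max(tol, 1e-8)) {
    stop(sprintf("eigenvector centrality did not converge within %.0f iterations",
                 2^n_squarings), call. = FALSE)
  }
  tibble(unit_id = net$labels, year = net$year, eigenvector = v)
}

#' All node-level metrics of a network
#'
#' Joins [degree_centrality()], [clustering_coefficient()] and
#' [eigenvector_centrality()] into one tidy table.
#'
#' @inheritParams eigenvector_centrality
#' @return A tibble: `unit_id`, `year`, `indegree`, `outdegree`,
#'   `clustering`, `eigenvector`.
#' @export
node_metrics <- function(net, direction = "in", tol = 1e-10,
                         max_iter = 1e9) {
  deg <- degree_centrality(net)
  cc <- clustering_coefficient(net)
  ev <- eigenvector_centrality(net, direction = direction, tol = tol,
                               max_iter = max_iter)
  out <- left_join(deg, cc, by = c("unit_id", "year"))
  left_join(out, ev, by = c("unit_id", "year"))
}
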