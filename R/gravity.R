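#' Gravity attraction matrix for one panel year
#'
#' Computes the spatial-interaction (gravity) matrix between regional units:
#' the attraction between two units is the product of their masses (GDP times
#' population each) divided by the squared distance between them,
#' \deqn{R_{ij} = GDP_i P_i \, GDP_j P_j / d_{ij}^2,}
#' in units of (10,000 yuan x 10,000 people) / km^2. The matrix is exactly
#' symmetric and the diagonal is defined as 0.
#'
#' @param panel A panel restricted to one year, or a multi-year panel with
#'   `year` given. Needs columns `unit_id`, `year`, `x_coord`, `y_coord`,
#'   `gdp`, `population` (coordinates are ignored when `distances` is
#'   supplied).
#' @param year Which year to use when `panel` spans several.
#' @param distances Optional pre-computed symmetric distance matrix (km),
#'   ordered and ideally dimnamed like the units; by default Euclidean
#'   distances between planar coordinates.
#' @param sqrt_masses If `TRUE`, use the square-root-of-mass variant
#'   \eqn{\sqrt{GDP_i P_i}\sqrt{GDP_j P_j}/d_{ij}^2} sometimes seen in the
#'   regional-science literature. Default `FALSE`: the plain product form.
#' @return An object of class `gravity_matrix`: list with `year`, `labels`
#'   and the `values` matrix.
#' @examples
#' p <- tibble::tibble(unit_id = c("a", "b"), year = 2018,
#'                     x_coord = c(0, 1), y_coord = 0,
#'                     gdp = 1, population = 1)
#' compute_gravity(p)$values
#' @export
compute_gravity <- function(panel, year = NULL, distances = NULL,
                            sqrt_masses = FALSE) {
  need <- c("unit_id", "year", "gdp", "population")
  missing_cols <- setdiff(need, names(panel))
  if (length(missing_cols) > 0) {
    stop(sprintf("panel is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (is.null(year)) {
    year <- unique(panel$year)
    if (length(year) != 1) {
      stop("panel spans several years; supply `year`", call. = FALSE)
    }
  }
  slice <- panel[panel$year == year, , drop = FALSE]
  slice <- slice[order(slice$unit_id), , drop = FALSE]
  n <- nrow(slice)
  if (n < 2) stop("need at least 2 units", call. = FALSE)
  if (any(slice$gdp <= 0) || any(slice$population <= 0)) {
    stop("gdp and population must be strictly positive", call. = FALSE)
  }
  labels <- slice$unit_id

  if (is.null(distances)) {
    if (!all(c("x_coord", "y_coord") %in% names(slice))) {
      stop("panel is missing required column(s): x_coord, y_coord",
           call. = FALSE)
    }
    d <- as.matrix(dist(cbind(slice$x_coord, slice$y_coord)))
  } else {
    d <- as.matrix(distances)
    if (!all(dim(d) == n)) stop("`distances` has the wrong dimension",
                                call. = FALSE)
  }
  dd <- d; diag(dd) <- Inf
  zero <- which(dd <= 0, arr.ind = TRUE)
  if (nrow(zero) > 0) {
    stop(sprintf("coincident units (zero distance): %s and %s",
                 labels[zero[1, 1]], labels[zero[1, 2]]), call. = FALSE)
  }

  mass <- slice$gdp * slice$population
  if (sqrt_masses) mass <- sqrt(mass)
  values <- outer(mass, mass) / d^2
  diag(values) <- 0
  values <- (values + t(values)) / 2  # enforce exact symmetry
  dimnames(values) <- list(labels, labels)

  structure(list(year = year, labels = labels, values = values),
            class = "gravity_matrix")
}

#' @export
print.gravity_matrix <- function(x, ...) {
  cat(sprintf("<gravity_matrix> %d units, year %s\n",
              length(x$labels), format(x$year)))
  cat(sprintf("  off-diagonal range [%.4g, %.4g]\n",
              min(x$values[upper.tri(x$values)]),
              max(x$values[upper.tri(x$values)])))
  invisible(x)
}

#' Binarize a gravity matrix into a directed network
#'
#' Thresholds each row of the gravity matrix by its own mean: unit `i` sends
#' an edge to `j` whenever the attraction `R_ij` strictly exceeds the mean of
#' row `i`. Although the gravity matrix is symmetric, differing row means
#' make the resulting adjacency directed. Entries exactly equal to the row
#' mean (for example a constant row) produce no edge.
#'
#' @param gravity A [compute_gravity()] result.
#' @param threshold_includes_diagonal If `FALSE` (default) the row mean is
#'   taken over the `n - 1` off-diagonal entries; the structural 0 on the
#'   diagonal would otherwise bias every threshold downward.
#' @return An object of class `econet_network`: list with `year`, `labels`,
#'   binary `adjacency` (rows = senders) and `density`.
#' @export
binarize <- function(gravity, threshold_includes_diagonal = FALSE) {
  stopifnot(inherits(gravity, "gravity_matrix"))
  R <- gravity$values
  n <- nrow(R)
  if (n < 2) stop("need at least 2 units", call. = FALSE)
  denom <- if (threshold_includes_diagonal) n else n - 1
  thr <- rowSums(R) / denom  # diagonal is 0, so rowSums = off-diagonal sums
  A <- 1L * (R > thr)
  diag(A) <- 0L
  dimnames(A) <- dimnames(R)
  structure(list(year = gravity$year, labels = gravity$labels,
                 adjacency = A, density = sum(A) / (n * (n - 1))),
            class = "econet_network")
}

#' Wrap an adjacency matrix as a network object
#'
#' @param adjacency Square binary matrix, zero diagonal; entry `[i, j] = 1`
#'   means an edge from `i` to `j`.
#' @param year Optional year label.
#' @param labels Optional unit labels (default from dimnames, else `V1..Vn`).
#' @return An `econet_network` object.
#' @export
as_econet_network <- function(adjacency, year = NA_integer_, labels = NULL) {
  A <- as.matrix(adjacency)
  if (nrow(A) != ncol(A)) stop("adjacency must be square", call. = FALSE)
  if (any(A != 0 & A != 1)) stop("adjacency must be binary", call. = FALSE)
  if (any(diag(A) != 0)) stop("adjacency diagonal must be 0", call. = FALSE)
  n <- nrow(A)
  labels <- labels %||% rownames(A) %||% sprintf("V%d", seq_len(n))
  storage.mode(A) <- "integer"
  dimnames(A) <- list(labels, labels)
  structure(list(year = year, labels = labels, adjacency = A,
                 density = sum(A) / (n * (n - 1))),
            class = "econet_network")
}

#' @export
print.econet_network <- function(x, ...) {
  cat(sprintf("<econet_network> %d nodes, %d edges, density %.3f, year %s\n",
              length(x$labels), sum(x$adjacency), x$density, format(x$year)))
  invisible(x)
}

#' Density of a directed network
#'
#' Edges divided by the `n (n - 1)` ordered pairs.
#'
#' @param net An `econet_network`.
#' @return A fraction in `[0, 1]`.
#' @export
network_density <- function(net) {
  stopifnot(inherits(net, "econet_network"))
  n <- length(net$labels)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  sum(net$adjacency) / (n * (n - 1))
}

#' Export a gravity matrix or network
#'
#' `write_gravity_csv()` writes the square gravity matrix as CSV with a
#' labelled header row and a leading label column. `write_edgelist()` writes
#' the directed edges as a two-column (source, target) CSV.
#' `write_graphml()` writes GraphML via the igraph package.
#'
#' @param gravity A `gravity_matrix`.
#' @param net An `econet_network`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_gravity_csv <- function(gravity, path) {
  stopifnot(inherits(gravity, "gravity_matrix"))
  out <- as_tibble(gravity$values)
  out <- dplyr::bind_cols(tibble(unit_id = gravity$labels), out)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_gravity_csv
#' @export
write_edgelist <- function(net, path) {
  stopifnot(inherits(net, "econet_network"))
  idx <- which(net$adjacency == 1L, arr.ind = TRUE)
  edges <- tibble(source = net$labels[idx[, 1]],
                  target = net$labels[idx[, 2]])
  edges <- dplyr::arrange(edges, .data$source, .data$target)
  readr::write_csv(edges, path)
  invisible(path)
}

#' @rdname write_gravity_csv
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "econet_network"))
  g <- igraph::graph_from_adjacency_matrix(net$adjacency, mode = "directed")
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
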