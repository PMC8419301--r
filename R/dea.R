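#' Radial input-oriented DEA distance function
#'
#' Solves the envelopment linear program for one evaluated activity against
#' a frontier technology: minimize the radial input contraction
#' \eqn{\theta} subject to a frontier-weighted input combination no larger
#' than \eqn{\theta x_0} component-wise, a frontier-weighted output
#' combination at least \eqn{y_0}, nonnegative intensity weights, and (VRS
#' only) weights summing to one. Same-period scores lie in `(0, 1]`;
#' cross-period scores may exceed 1, and cross-period VRS programs can be
#' infeasible, which is reported rather than an error.
#'
#' @param x0,y0 Input and output vectors of the evaluated activity.
#' @param X,Y Frontier input (units x inputs) and output (units x outputs)
#'   matrices; all entries strictly positive.
#' @param rts `"crs"` (constant returns) or `"vrs"` (variable returns:
#'   convexity constraint added).
#' @param tol Simplex pivot tolerance.
#' @return A list: `theta` (NA if infeasible), `lambda` (intensity weights),
#'   `feasible`.
#' @examples
#' # 1 input / 1 output: theta is relative productivity (y/x) / max(y/x)
#' X <- cbind(c(1, 2, 4)); Y <- cbind(c(1, 3, 4))
#' sapply(1:3, function(i) dea_score(X[i, ], Y[i, ], X, Y)$theta)
#' @export
dea_score <- function(x0, y0, X, Y, rts = c("crs", "vrs"), tol = 1e-8) {
  rts <- match.arg(rts)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); m <- ncol(X); s <- ncol(Y)
  stopifnot(length(x0) == m, length(y0) == s, nrow(Y) == n)
  if (any(X <= 0) || any(Y <= 0) || any(x0 <= 0) || any(y0 <= 0)) {
    stop("DEA data must be strictly positive", call. = FALSE)
  }
  # Radial scores are units-invariant, so rescale every column by its
  # frontier mean: keeps the simplex tableau well conditioned when inputs
  # and outputs live on very different scales.
  cx <- colMeans(X); cy <- colMeans(Y)
  X <- sweep(X, 2, cx, "/"); x0 <- x0 / cx
  Y <- sweep(Y, 2, cy, "/"); y0 <- y0 / cy
  # variables: theta, lambda_1..lambda_n
  objective <- c(1, rep(0, n))
  solve_once <- function(fx, fy) {
    Xa <- sweep(X, 2, fx, "*"); x0a <- x0 * fx
    Ya <- sweep(Y, 2, fy, "*"); y0a <- y0 * fy
    A1 <- cbind(-x0a, t(Xa)); b1 <- rep(0, m)   # X'lam <= theta x0
    A2 <- cbind(0, t(Ya)); b2 <- y0a            # Y'lam >= y0
    tryCatch({
      if (rts == "vrs") {
        boot::simplex(objective, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                      A3 = matrix(c(0, rep(1, n)), nrow = 1), b3 = 1,
                      eps = tol)
      } else {
        boot::simplex(objective, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                      eps = tol)
      }
    }, error = function(e) NULL)
  }
  # Exactly collinear data (common on piecewise frontiers) can stall the
  # pivoting on a degenerate basis. Radial scores are invariant to column
  # rescaling, so retry stalled solves under fixed rescalings: the program
  # is mathematically identical, only the pivot path changes.
  res <- solve_once(rep(1, m), rep(1, s))
  attempt <- 0
  while (is.null(res) && attempt < 12) {
    attempt <- attempt + 1
    fx <- exp(0.6 * sin(attempt * seq_len(m) * 1.7 + 0.3))
    fy <- exp(0.6 * cos(attempt * seq_len(s) * 2.3 + 0.7))
    res <- solve_once(fx, fy)
  }
  if (is.null(res)) {
    stop("DEA linear program stalled on a degenerate basis", call. = FALSE)
  }
  if (res$solved == -1) {
    return(list(theta = NA_real_, lambda = rep(NA_real_, n),
                feasible = FALSE))
  }
  if (res$solved != 1) {
    stop("DEA linear program did not converge", call. = FALSE)
  }
  list(theta = unname(res$value), lambda = unname(res$soln[-1]),
       feasible = TRUE)
}

panel_tech <- function(panel, year) {
  slice <- panel[panel$year == year, , drop = FALSE]
  slice <- slice[order(slice$unit_id), , drop = FALSE]
  list(units = slice$unit_id,
       X = as.matrix(slice[, dea_input_columns]),
       Y = as.matrix(slice[, dea_output_columns]))
}

#' DEA efficiency scores for panel years
#'
#' Scores every unit-year activity against a frontier built from all units
#' of a period (by default its own period). Input orientation throughout:
#' the score is the largest feasible proportional shrinkage of the three
#' health-care inputs holding outputs attainable, so a score below one
#' quantifies resource waste under the existing input bundle.
#'
#' @param panel A province-year panel (see [validate_panel()]).
#' @param rts `"crs"` or `"vrs"`.
#' @param years Activity years to score (default all).
#' @param frontier_year Fix the frontier period (default: same period as the
#'   activity).
#' @param tol Simplex tolerance passed to [dea_score()].
#' @return A tibble: `unit_id`, `year`, `frontier_year`, `rts`, `theta`,
#'   `feasible`.
#' @export
dea_efficiency <- function(panel, rts = c("crs", "vrs"), years = NULL,
                           frontier_year = NULL, tol = 1e-8) {
  rts <- match.arg(rts)
  validate_panel(panel)
  years <- years %||% sort(unique(panel$year))
  purrr::map_dfr(years, function(yr) {
    fy <- frontier_year %||% yr
    act <- panel_tech(panel, yr)
    fro <- panel_tech(panel, fy)
    scores <- purrr::map(seq_along(act$units), function(i) {
      dea_score(act$X[i, ], act$Y[i, ], fro$X, fro$Y, rts = rts, tol = tol)
    })
    tibble(unit_id = act$units, year = yr, frontier_year = fy, rts = rts,
           theta = purrr::map_dbl(scores, "theta"),
           feasible = purrr::map_lgl(scores, "feasible"))
  })
}
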