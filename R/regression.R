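#' Assemble the analysis panel: TFP change joined with network position
#'
#' Runs the network stages (gravity, thresholding, node metrics) for every
#' panel year and the CRS Malmquist stage for every adjacent-year
#' transition, then aligns each transition's TFP change with the network
#' metrics of one of its endpoint years.
#'
#' With `align = "end_year"` (default) the transition `t -> t+1` is labelled
#' by its end year and joined with year-`(t+1)` metrics, so a panel with
#' `Y` calendar years yields `Y - 1` analysis years per unit. The default
#' synthetic configuration carries one lead-in year for exactly this
#' reason: six data years produce five analysis years per unit.
#'
#' @param panel A balanced province-year panel.
#' @param align `"end_year"` or `"start_year"`: which endpoint's network
#'   metrics (and year label) a transition is matched with.
#' @param malm Optional precomputed [malmquist()] records (any `components`);
#'   computed CRS-only when `NULL`.
#' @param metrics Optional precomputed per-year [node_metrics()] table;
#'   computed when `NULL`.
#' @param ... Passed to [compute_gravity()] / [binarize()] /
#'   [node_metrics()] flags: `sqrt_masses`, `threshold_includes_diagonal`,
#'   `direction`.
#' @param sqrt_masses,threshold_includes_diagonal,direction Stage flags, see
#'   the respective functions.
#' @return A tibble: `unit_id`, `year`, `tfpch`, `indegree`, `outdegree`,
#'   `eigenvector`, `clustering`, `region`.
#' @export
analysis_panel <- function(panel, align = c("end_year", "start_year"),
                           malm = NULL, metrics = NULL,
                           sqrt_masses = FALSE,
                           threshold_includes_diagonal = FALSE,
                           direction = "in") {
  align <- match.arg(align)
  validate_panel(panel)
  if (is.null(metrics)) {
    years <- sort(unique(panel$year))
    metrics <- purrr::map_dfr(years, function(yr) {
      g <- compute_gravity(panel, year = yr, sqrt_masses = sqrt_masses)
      net <- binarize(g, threshold_includes_diagonal = threshold_includes_diagonal)
      node_metrics(net, direction = direction)
    })
  }
  if (is.null(malm)) malm <- malmquist(panel, components = "crs")
  malm <- malm[malm$feasible, , drop = FALSE]
  malm$year <- if (align == "end_year") malm$to_year else malm$from_year
  regions <- dplyr::distinct(panel[, c("unit_id", "year", "region")])
  out <- malm |>
    select("unit_id", "year", "tfpch") |>
    left_join(metrics, by = c("unit_id", "year")) |>
    left_join(regions, by = c("unit_id", "year")) |>
    arrange(.data$unit_id, .data$year)
  out
}

#' Descriptive statistics of the analysis variables
#'
#' N, mean, sample standard deviation (n - 1 denominator), minimum and
#' maximum per variable. Values are returned at full precision; round for
#' display.
#'
#' @param apanel An [analysis_panel()] table (or any data frame).
#' @param vars Variables to describe.
#' @return A tibble: `variable`, `n`, `mean`, `sd`, `min`, `max`.
#' @export
descriptives <- function(apanel,
                         vars = c("tfpch", "indegree", "eigenvector",
                                  "clustering")) {
  if (nrow(apanel) == 0) stop("empty panel", call. = FALSE)
  missing_cols <- setdiff(vars, names(apanel))
  if (length(missing_cols) > 0) {
    stop(sprintf("missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  purrr::map_dfr(vars, function(v) {
    x <- apanel[[v]]
    tibble(variable = v, n = sum(!is.na(x)),
           mean = mean(x, na.rm = TRUE), sd = sd(x, na.rm = TRUE),
           min = min(x, na.rm = TRUE), max = max(x, na.rm = TRUE))
  })
}

#' Pooled OLS of TFP change on each network metric
#'
#' Fits one model per focal metric -- indegree, eigenvector centrality,
#' clustering coefficient -- regressing TFP change on the metric plus region
#' and year dummies (reference categories dropped), with conventional
#' (non-robust) standard errors. One regressor per model, never all three
#' jointly: the three centralities are strongly collinear and the published
#' presentation of this design is three single-regressor columns.
#'
#' @param apanel An [analysis_panel()] table with at least two regions and
#'   two years represented.
#' @param focal Metrics to use as focal regressors.
#' @return An object of class `tfp_models` (list of `lm` fits plus
#'   metadata) with [tidy()], [glance()], `print()` and
#'   [format_tfp_table()] methods.
#' @export
fit_tfp_models <- function(apanel,
                           focal = c("indegree", "eigenvector",
                                     "clustering")) {
  need <- c("tfpch", focal, "region", "year")
  missing_cols <- setdiff(need, names(apanel))
  if (length(missing_cols) > 0) {
    stop(sprintf("missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  dat <- apanel |>
    filter(dplyr::if_all(dplyr::all_of(need[need != "region"]), ~ !is.na(.x))) |>
    mutate(region = factor(.data$region), year_f = factor(.data$year))
  if (nlevels(dat$region) < 2) {
    stop("need at least 2 regions represented", call. = FALSE)
  }
  if (nlevels(dat$year_f) < 2) {
    stop("need at least 2 years represented", call. = FALSE)
  }
  fits <- lapply(focal, function(metric) {
    fm <- reformulate(c(metric, "region", "year_f"), response = "tfpch")
    fit <- lm(fm, data = dat)
    aliased <- is.na(coef(fit))
    if (any(aliased)) {
      stop(sprintf("collinear terms in model `%s`: %s", metric,
                   paste(names(coef(fit))[aliased], collapse = ", ")),
           call. = FALSE)
    }
    fit
  })
  names(fits) <- focal
  structure(list(fits = fits, focal = focal, n_obs = nrow(dat),
                 controls = c("region", "year")),
            class = "tfp_models")
}

model_stats <- function(fit) {
  sm <- summary(fit)
  y <- stats::model.response(stats::model.frame(fit))
  tss <- sum((y - mean(y))^2)
  degenerate <- !is.finite(sm$adj.r.squared) || tss < 1e-16
  list(coefs = sm$coefficients,
       adj_r_squared = if (degenerate) 0 else sm$adj.r.squared,
       r_squared = if (degenerate) 0 else sm$r.squared)
}

#' @export
tidy.tfp_models <- function(x, ...) {
  purrr::map_dfr(x$focal, function(metric) {
    cf <- model_stats(x$fits[[metric]])$coefs
    tibble(model = metric, term = rownames(cf),
           estimate = cf[, 1], std.error = cf[, 2],
           statistic = cf[, 3], p.value = cf[, 4])
  })
}

#' @export
glance.tfp_models <- function(x, ...) {
  purrr::map_dfr(x$focal, function(metric) {
    st <- model_stats(x$fits[[metric]])
    tibble(model = metric, n_obs = x$n_obs,
           r.squared = st$r_squared, adj.r.squared = st$adj_r_squared)
  })
}

sig_stars <- function(p) {
  ifelse(p < 0.01, "***", ifelse(p < 0.05, "**", ifelse(p < 0.1, "*", "")))
}

#' Plain-text three-column regression table
#'
#' Formats the fitted models in the conventional journal layout: one column
#' per focal metric, coefficient with significance stars over its
#' t-statistic in parentheses, then observations, control rows and adjusted
#' R-squared.
#'
#' @param x A `tfp_models` object.
#' @param digits Decimal places for coefficients.
#' @return A character vector of table lines.
#' @export
format_tfp_table <- function(x, digits = 3) {
  stopifnot(inherits(x, "tfp_models"))
  td <- tidy(x)
  gl <- glance(x)
  cell <- function(metric, row) {
    hit <- td[td$model == metric & td$term == row, ]
    if (nrow(hit) == 0) return(c("-", "-"))
    c(sprintf("%.*f%s", digits, hit$estimate, sig_stars(hit$p.value)),
      sprintf("(%.3f)", hit$statistic))
  }
  rows <- c(stats::setNames(x$focal, x$focal), Constant = "(Intercept)")
  lines <- c(paste(c("Variables", rep("TFP change", length(x$focal))),
                   collapse = "\t"))
  for (rn in names(rows)) {
    vals <- sapply(x$focal, function(m) cell(m, rows[[rn]]))
    lines <- c(lines,
               paste(c(rn, vals[1, ]), collapse = "\t"),
               paste(c("", vals[2, ]), collapse = "\t"))
  }
  lines <- c(lines,
             paste(c("Observations", rep(x$n_obs, length(x$focal))),
                   collapse = "\t"),
             paste(c("Region", rep("Control", length(x$focal))),
                   collapse = "\t"),
             paste(c("Year", rep("Control", length(x$focal))),
                   collapse = "\t"),
             paste(c("Adj R-squared",
                     sprintf("%.3f", gl$adj.r.squared)), collapse = "\t"))
  lines
}

#' @export
print.tfp_models <- function(x, ...) {
  cat(format_tfp_table(x), sep = "\n")
  invisible(x)
}
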