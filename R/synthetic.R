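#' Configuration for the synthetic province-panel generator
#'
#' Bundles and validates every knob of the data-generating process used by
#' [generate_panel()]. The defaults describe the study conditions the rest of
#' the package is validated against: 31 provincial units observed over six
#' calendar years (2013--2018, so that five year-to-year transitions end in
#' the five analysis years 2014--2018), a constant-returns Cobb-Douglas
#' health-care production frontier over three inputs, a mild yearly frontier
#' regression, planted radial inefficiency, a linear effect of network
#' position on log TFP change, and a three-group latent regional typology.
#'
#' @param n_units Number of regional units (>= 3).
#' @param n_years Number of calendar years in the panel (>= 2).
#' @param first_year First calendar year label.
#' @param n_groups Number of latent typology groups (<= `n_units`).
#' @param frontier_elasticities Nonnegative Cobb-Douglas elasticities of the
#'   three inputs (institutions, personnel, beds). The default sums to one,
#'   giving constant returns to scale so that radial DEA can recover the
#'   planted efficiencies exactly in the noiseless limit.
#' @param tech_change_rate Multiplicative frontier shift per year. Values
#'   below one shrink the attainable output set year on year, which is what
#'   the package's Malmquist stage should report as `techch` equal to this
#'   rate on noiseless data.
#' @param inefficiency_spread Width of the uniform distribution of planted
#'   inefficiency: baseline efficiency is drawn from
#'   `1 - U(0, inefficiency_spread)`, so the default 0.5 keeps true CRS
#'   efficiency in `[0.5, 1]`. Zero disables the inefficiency process
#'   entirely (every unit-year is fully efficient).
#' @param effect_beta Planted linear coefficient of the standardized network
#'   position score (standardized indegree of the first-year network) on log
#'   TFP change.
#' @param noise_sd Standard deviation of multiplicative log-normal output
#'   noise.
#' @param seed Integer seed; every stochastic draw in [generate_panel()] is
#'   a deterministic function of it.
#' @return A validated list of class `synthetic_config`.
#' @examples
#' cfg <- synthetic_config(n_units = 10, n_years = 3, seed = 1)
#' @export
synthetic_config <- function(n_units = 31,
                             n_years = 6,
                             first_year = 2013,
                             n_groups = 3,
                             frontier_elasticities = c(0.3, 0.4, 0.3),
                             tech_change_rate = 0.99,
                             inefficiency_spread = 0.5,
                             effect_beta = 0.02,
                             noise_sd = 0.05,
                             seed = 20180823) {
  cfg <- list(
    n_units = check_count(n_units, "n_units", min = 3),
    n_years = check_count(n_years, "n_years", min = 2),
    first_year = check_count(first_year, "first_year", min = 1800),
    n_groups = check_count(n_groups, "n_groups", min = 1),
    frontier_elasticities = frontier_elasticities,
    tech_change_rate = check_scalar(tech_change_rate, "tech_change_rate",
                                    min = 1e-6),
    inefficiency_spread = check_scalar(inefficiency_spread,
                                       "inefficiency_spread",
                                       min = 0, max = 0.95),
    effect_beta = check_scalar(effect_beta, "effect_beta"),
    noise_sd = check_scalar(noise_sd, "noise_sd", min = 0),
    seed = check_count(seed, "seed", min = 0)
  )
  if (cfg$n_groups > cfg$n_units) {
    stop_field("n_groups", "must not exceed n_units")
  }
  el <- cfg$frontier_elasticities
  if (!is.numeric(el) || length(el) != 3 || anyNA(el) || any(el < 0) ||
      sum(el) <= 0) {
    stop_field("frontier_elasticities",
               "must be 3 nonnegative numbers with a positive sum")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config>\n")
  cat(sprintf("  %d units x %d years (%d-%d), %d latent groups\n",
              x$n_units, x$n_years, x$first_year,
              x$first_year + x$n_years - 1, x$n_groups))
  cat(sprintf("  elasticities (%s), tech change %.3f/yr\n",
              paste(format(x$frontier_elasticities), collapse = ", "),
              x$tech_change_rate))
  cat(sprintf("  inefficiency spread %.2f, effect beta %.3f, noise sd %.3f, seed %d\n",
              x$inefficiency_spread, x$effect_beta, x$noise_sd, x$seed))
  invisible(x)
}

# Group sizes decrease from periphery to core (weights n_groups:1),
# echoing the usual many-periphery / few-core shape of regional systems.
group_sizes <- function(n_units, n_groups) {
  w <- rev(seq_len(n_groups))
  cuts <- round(cumsum(w / sum(w)) * n_units)
  sizes <- diff(c(0, cuts))
  if (any(sizes < 1)) {  # tiny configurations: fall back to near-equal split
    sizes <- rep(n_units %/% n_groups, n_groups)
    sizes[seq_len(n_units %% n_groups)] <- sizes[seq_len(n_units %% n_groups)] + 1
  }
  sizes
}

#' Generate a synthetic province panel with known ground truth
#'
#' Draws a balanced province-year panel with the statistical structure the
#' downstream analysis assumes, together with the ground truth needed for
#' recovery tests.
#'
#' The generating process, in order:
#' \enumerate{
#'   \item Units are split into `n_groups` latent groups from periphery
#'     (group 1: low mass, western coordinates) to core (highest group: high
#'     mass, eastern coordinates). Planar coordinates (km) are drawn around
#'     west-to-east group centres; the categorical `region` label is assigned
#'     as three contiguous spatial blocks by longitude terciles.
#'   \item GDP and population are log-normal with group-specific locations
#'     (heavy-tailed masses). GDP grows at a common 7\% per year, which
#'     rescales every gravity entry equally and therefore leaves the
#'     thresholded network identical across years.
#'   \item The three health-care inputs follow common national ratios per
#'     10,000 population, so input mixes are proportional across units and
#'     the piecewise-linear DEA frontier coincides with the smooth generating
#'     frontier.
#'   \item Outputs come from a Cobb-Douglas frontier over the inputs, shifted
#'     by `tech_change_rate` each year, scaled by the planted efficiency and
#'     hit by multiplicative log-normal noise. Bed utilization is the
#'     intensity margin (does not scale with unit size); outpatient visits
#'     are the volume margin.
#'   \item Baseline efficiency is `1 - U(0, inefficiency_spread)`; the
#'     smallest unit is pinned at efficiency 1 every year so the frontier is
#'     anchored. Efficiency then drifts by `exp(effect_beta * z * (t - t_mid))`
#'     (capped at 1), where `z` is the unit's standardized indegree in the
#'     binarized gravity network, so that log TFP change carries a linear
#'     planted effect of network position with coefficient `effect_beta`.
#'     With `inefficiency_spread = 0` there is no inefficiency process to
#'     modulate and every unit-year has efficiency exactly 1.
#' }
#'
#' @param config A [synthetic_config()].
#' @return A list of class `panel_sim` with elements
#'   \describe{
#'     \item{panel}{tibble of province-year records (see [validate_panel()]
#'       for the column contract).}
#'     \item{truth}{list with `efficiency` (tibble: unit_id, year,
#'       true_efficiency), `groups` (tibble: unit_id, true_group),
#'       `true_beta`, and `frontier_params`.}
#'   }
#' @examples
#' sim <- generate_panel(synthetic_config(n_units = 8, n_years = 3, seed = 1))
#' head(sim$panel)
#' @export
generate_panel <- function(config = synthetic_config()) {
  if (!inherits(config, "synthetic_config")) {
    config <- do.call(synthetic_config, as.list(config))
  }
  withr::with_seed(config$seed, generate_panel_impl(config))
}

generate_panel_impl <- function(cfg) {
  n <- cfg$n_units
  yrs <- cfg$first_year + seq_len(cfg$n_years) - 1L
  unit_id <- sprintf("P%02d", seq_len(n))

  sizes <- group_sizes(n, cfg$n_groups)
  group <- rep(seq_len(cfg$n_groups), times = sizes)
  n_hub_groups <- cfg$n_groups - 1

  # Masses: a small scattered periphery (group 1) and one or more compact
  # "hub" groups whose log-mass locations interpolate a secondary-centre ->
  # primary-core gradient. Periphery masses are dispersed (heavy tail);
  # hub masses are tight, which keeps each hub's attraction comparable
  # across its members and the thresholded edges stable.
  hub_frac <- if (n_hub_groups > 1) (group - 2) / (n_hub_groups - 1) else
    rep(1, n)
  mu_pop <- ifelse(group == 1, log(300),
                   log(3000) + hub_frac * (log(4200) - log(3000)))
  mu_gdp <- ifelse(group == 1, log(3e6),
                   log(1.5e8) + hub_frac * (log(5.5e8) - log(1.5e8)))
  sd_pop <- ifelse(group == 1, 0.12, 0.03)
  sd_gdp <- ifelse(group == 1, 0.15, 0.04)
  population <- rlnorm(n, meanlog = mu_pop, sdlog = sd_pop)
  gdp0 <- rlnorm(n, meanlog = mu_gdp, sdlog = sd_gdp)

  # Geography: the periphery sits on a jittered grid over a western block;
  # each hub group is a ring of near-evenly spaced cities further east, so
  # that within-hub pair distances (and hence mutual attraction) are
  # comparable around the ring.
  x_coord <- numeric(n); y_coord <- numeric(n)
  n1 <- sizes[1]
  nr <- ceiling(sqrt(n1)); nc <- ceiling(n1 / nr)
  gx <- rep(seq(350, 850, length.out = nc), each = nr)[seq_len(n1)]
  gy <- rep(seq(1110, 1890, length.out = nr), times = nc)[seq_len(n1)]
  x_coord[group == 1] <- gx + rnorm(n1, 0, 30)
  y_coord[group == 1] <- gy + rnorm(n1, 0, 30)
  for (g in seq_len(n_hub_groups)) {
    idx <- which(group == g + 1)
    ng <- length(idx)
    hf <- if (n_hub_groups > 1) (g - 1) / (n_hub_groups - 1) else 1
    centre_x <- 1900 + hf * 1600
    centre_y <- 1500 - hf * 300
    radius <- 250 - hf * 70
    ang <- 2 * pi * (seq_len(ng) - 1) / max(ng, 1) + rnorm(ng, 0, 0.06)
    rad <- radius * exp(rnorm(ng, 0, 0.06))
    x_coord[idx] <- centre_x + rad * cos(ang)
    y_coord[idx] <- centre_y + rad * sin(ang)
  }
  # guarantee distinct locations (gravity needs d > 0)
  repeat {
    d <- as.matrix(dist(cbind(x_coord, y_coord)))
    diag(d) <- Inf
    clash <- which(d < 1, arr.ind = TRUE)
    if (nrow(clash) == 0) break
    i <- clash[1, 1]
    x_coord[i] <- x_coord[i] + runif(1, 1, 5)
  }
  region <- cut(x_coord, breaks = stats::quantile(x_coord, c(0, 1/3, 2/3, 1)),
                labels = c("west", "central", "east"), include.lowest = TRUE)
  region <- as.character(region)

  # Inputs: common national ratios per 10,000 population.
  input_mix <- c(institutions = 6.2, personnel = 130, beds = 112)
  X <- outer(population, input_mix)

  # Planted network-position score from the first-year network.
  base_panel <- tibble(
    unit_id = unit_id, year = yrs[1], x_coord = x_coord, y_coord = y_coord,
    gdp = gdp0, population = population
  )
  gravity <- compute_gravity(base_panel)
  net <- binarize(gravity)
  indeg <- colSums(net$adjacency)
  z <- if (sd(indeg) > 0) as.numeric(scale(indeg)) else rep(0, n)

  # Planted efficiency: baseline draw, frontier anchor, network drift.
  anchor <- which.min(population)
  if (cfg$inefficiency_spread > 0) {
    eff0 <- 1 - runif(n, 0, cfg$inefficiency_spread)
    eff0[anchor] <- 1
    t_mid <- mean(seq_len(cfg$n_years))
    eff <- sapply(seq_len(cfg$n_years), function(ti) {
      e <- pmin(1, eff0 * exp(cfg$effect_beta * z * (ti - t_mid)))
      e[anchor] <- 1
      e
    })
  } else {
    eff <- matrix(1, n, cfg$n_years)
  }

  alpha <- cfg$frontier_elasticities
  frontier_volume <- exp(log(X) %*% alpha)  # Cobb-Douglas over the 3 inputs

  rows <- purrr::map(seq_len(cfg$n_years), function(ti) {
    shift <- cfg$tech_change_rate^(ti - 1)
    noise1 <- exp(rnorm(n, 0, cfg$noise_sd))
    noise2 <- exp(rnorm(n, 0, cfg$noise_sd))
    tibble(
      unit_id = unit_id,
      year = yrs[ti],
      x_coord = x_coord,
      y_coord = y_coord,
      gdp = gdp0 * 1.07^(ti - 1),
      population = population,
      institutions = X[, 1],
      personnel = X[, 2],
      beds = X[, 3],
      bed_utilization = pmin(200, 88 * eff[, ti] * shift * noise1),
      outpatient_visits = 0.4 * as.numeric(frontier_volume) *
        eff[, ti] * shift * noise2,
      region = region
    )
  })
  panel <- dplyr::bind_rows(rows)
  validate_panel(panel)

  truth <- list(
    efficiency = tibble(
      unit_id = rep(unit_id, times = cfg$n_years),
      year = rep(yrs, each = n),
      true_efficiency = as.numeric(eff)
    ),
    groups = tibble(unit_id = unit_id, true_group = group),
    network_score = tibble(unit_id = unit_id, indegree = indeg, z = z),
    true_beta = cfg$effect_beta,
    # the same effect expressed per unit of raw indegree (the regression
    # stage's focal scale); NA when the network is degenerate
    beta_indegree = if (sd(indeg) > 0) cfg$effect_beta / sd(indeg)
      else NA_real_,
    frontier_params = list(
      elasticities = alpha,
      tech_change_rate = cfg$tech_change_rate
    )
  )
  structure(list(panel = panel, truth = truth, config = cfg),
            class = "panel_sim")
}

#' @export
print.panel_sim <- function(x, ...) {
  cat("<panel_sim>\n")
  cat(sprintf("  panel: %d rows (%d units x %d years)\n",
              nrow(x$panel), x$config$n_units, x$config$n_years))
  cat(sprintf("  truth: efficiency in [%.3f, 1], %d groups, beta %.3f\n",
              min(x$truth$efficiency$true_efficiency),
              x$config$n_groups, x$truth$true_beta))
  invisible(x)
}

#' Write / read a province panel as CSV
#'
#' `write_panel()` writes the panel as UTF-8 CSV with a header row and one
#' unit-year per row; `read_panel()` reads such a file back and validates it
#' (column contract, positivity, balance). The round trip is lossless.
#'
#' @param panel A province-year panel (see [validate_panel()]).
#' @param path File path.
#' @return `write_panel()` the path invisibly; `read_panel()` a validated
#'   tibble.
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  readr::write_csv(panel[, panel_columns], path)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  panel <- readr::read_csv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             unit_id = readr::col_character(),
                             region = readr::col_character(),
                             year = readr::col_integer(),
                             .default = readr::col_double()
                           ))
  validate_panel(panel)
  as_tibble(panel)
}
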