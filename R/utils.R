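# Shared column contracts and small validators.

panel_columns <- c(
  "unit_id", "year", "x_coord", "y_coord", "gdp", "population",
  "institutions", "personnel", "beds", "bed_utilization",
  "outpatient_visits", "region"
)
dea_input_columns <- c("institutions", "personnel", "beds")
dea_output_columns <- c("bed_utilization", "outpatient_visits")

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_count <- function(value, field, min) {
  if (length(value) != 1 || !is.numeric(value) || is.na(value) ||
      value != as.integer(value) || value < min) {
    stop_field(field, sprintf("must be a single integer >= %d", min))
  }
  as.integer(value)
}

check_scalar <- function(value, field, min = -Inf, max = Inf) {
  if (length(value) != 1 || !is.numeric(value) || is.na(value) ||
      value < min || value > max) {
    stop_field(field, sprintf("must be a single number in [%g, %g]", min, max))
  }
  as.numeric(value)
}

geometric_mean <- function(x) exp(mean(log(x)))

#' Validate a province-year panel
#'
#' Checks the column contract, positivity constraints, the bed-utilization
#' range and balance (every unit observed in every year) of a panel table.
#' Called by [read_panel()] and by every stage that consumes a panel.
#'
#' @param panel A data frame of province-year records.
#' @return The panel, invisibly, as a tibble (errors otherwise).
#' @export
validate_panel <- function(panel) {
  if (!is.data.frame(panel)) stop("`panel` must be a data frame", call. = FALSE)
  missing_cols <- setdiff(panel_columns, names(panel))
  if (length(missing_cols) > 0) {
    stop(sprintf("panel is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  panel <- as_tibble(panel)
  num_cols <- setdiff(panel_columns, c("unit_id", "region"))
  for (col in num_cols) {
    if (!is.numeric(panel[[col]]) || anyNA(panel[[col]])) {
      stop(sprintf("panel column `%s` must be numeric with no missing values",
                   col), call. = FALSE)
    }
  }
  pos_cols <- c("gdp", "population", dea_input_columns, dea_output_columns)
  for (col in pos_cols) {
    if (any(panel[[col]] <= 0)) {
      stop(sprintf("panel column `%s` must be strictly positive", col),
           call. = FALSE)
    }
  }
  if (any(panel$bed_utilization > 200)) {
    stop("panel column `bed_utilization` must lie in (0, 200]", call. = FALSE)
  }
  units <- unique(panel$unit_id)
  years <- sort(unique(panel$year))
  expected <- tidyr::expand_grid(unit_id = units, year = years)
  have <- dplyr::distinct(panel[, c("unit_id", "year")])
  if (nrow(have) != nrow(panel)) {
    stop("panel has duplicated unit-year rows", call. = FALSE)
  }
  missing_uy <- dplyr::anti_join(expected, have, by = c("unit_id", "year"))
  if (nrow(missing_uy) > 0) {
    stop(sprintf(
      "unbalanced panel; missing unit-years: %s",
      paste(sprintf("%s/%d", missing_uy$unit_id, missing_uy$year),
            collapse = ", ")), call. = FALSE)
  }
  invisible(panel)
}
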