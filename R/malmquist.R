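#' Malmquist total-factor-productivity index and decomposition
#'
#' Chains the input-oriented DEA distance functions of adjacent periods into
#' the geometric-mean Malmquist index. For unit `i` and transition
#' `t -> t+1`, with `D^s(a)` the CRS distance of the period-`a` activity
#' against the period-`s` frontier:
#' \deqn{effch = D^{t+1}(t+1) / D^t(t)}
#' \deqn{techch = \sqrt{ \frac{D^t(t+1)}{D^{t+1}(t+1)} \cdot
#'                       \frac{D^t(t)}{D^{t+1}(t)} }}
#' \deqn{tfpch = effch \times techch}
#' Efficiency change splits further into pure efficiency change
#' (`pech`, the same ratio computed under VRS, same-period frontiers only)
#' and scale efficiency change `sech = effch / pech`. Both identities
#' (`tfpch = effch * techch`, `effch = pech * sech`) hold to machine
#' precision by construction; a value above one is improvement, below one
#' regression.
#'
#' @param panel A balanced province-year panel with at least two years.
#' @param components `"all"` (default) computes the VRS programs needed for
#'   `pech`/`sech`; `"crs"` skips them (those columns are `NA`), roughly
#'   halving the number of linear programs when only `tfpch` is needed.
#' @param tol Simplex tolerance.
#' @return A tibble of per-unit, per-transition records: `unit_id`,
#'   `from_year`, `to_year`, `effch`, `techch`, `pech`, `sech`, `tfpch`,
#'   `feasible`. Records touched by an infeasible cross-period program are
#'   flagged `feasible = FALSE` (their index values are `NA`) and a count is
#'   messaged.
#' @export
malmquist <- function(panel, components = c("all", "crs"), tol = 1e-8) {
  components <- match.arg(components)
  validate_panel(panel)
  years <- sort(unique(panel$year))
  if (length(years) < 2) stop("need at least 2 years", call. = FALSE)
  tech <- lapply(years, function(y) panel_tech(panel, y))
  names(tech) <- as.character(years)
  units <- tech[[1]]$units
  n <- length(units)

  score_vec <- function(act, fro, rts) {
    vapply(seq_len(n), function(i) {
      dea_score(act$X[i, ], act$Y[i, ], fro$X, fro$Y, rts = rts,
                tol = tol)$theta
    }, numeric(1))
  }

  # same-period distances, reused across adjacent transitions
  d_same_crs <- sapply(tech, function(tc) score_vec(tc, tc, "crs"))
  d_same_vrs <- if (components == "all") {
    sapply(tech, function(tc) score_vec(tc, tc, "vrs"))
  } else NULL

  recs <- purrr::map_dfr(seq_len(length(years) - 1), function(ti) {
    t0 <- tech[[ti]]; t1 <- tech[[ti + 1]]
    d_t_t1 <- score_vec(t1, t0, "crs")   # period-(t+1) activity, frontier t
    d_t1_t <- score_vec(t0, t1, "crs")   # period-t activity, frontier t+1
    effch <- d_same_crs[, ti + 1] / d_same_crs[, ti]
    techch <- sqrt((d_t_t1 / d_same_crs[, ti + 1]) *
                     (d_same_crs[, ti] / d_t1_t))
    pech <- if (components == "all") {
      d_same_vrs[, ti + 1] / d_same_vrs[, ti]
    } else rep(NA_real_, n)
    tibble(unit_id = units,
           from_year = years[ti], to_year = years[ti + 1],
           effch = effch, techch = techch,
           pech = pech, sech = effch / pech,
           tfpch = effch * techch,
           feasible = is.finite(effch) & is.finite(techch))
  })
  n_bad <- sum(!recs$feasible)
  if (n_bad > 0) {
    message(sprintf("malmquist: %d record(s) flagged infeasible", n_bad))
  }
  recs
}

#' Per-unit geometric means of Malmquist components
#'
#' Summarises transition-level records into province means, the standard
#' presentation of a Malmquist table: the geometric mean of each component
#' over a unit's transitions, which preserves both decomposition identities.
#'
#' @param records Output of [malmquist()].
#' @return A tibble: `unit_id`, `n_transitions`, geometric-mean `effch`,
#'   `techch`, `pech`, `sech`, `tfpch`. Units with no feasible records are
#'   dropped with a warning.
#' @export
province_means <- function(records) {
  ok <- records[records$feasible, , drop = FALSE]
  dropped <- setdiff(unique(records$unit_id), unique(ok$unit_id))
  if (length(dropped) > 0) {
    warning(sprintf("units with no feasible records omitted: %s",
                    paste(dropped, collapse = ", ")))
  }
  out <- ok |>
    group_by(.data$unit_id) |>
    summarise(n_transitions = dplyr::n(),
              across(c("effch", "techch", "pech", "sech", "tfpch"),
                     geometric_mean),
              .groups = "drop")
  out
}

#' Check the Malmquist decomposition identities on a component table
#'
#' Recomposes `tfpch` from `effch * techch` and `effch` from `pech * sech`
#' and compares each against the tabulated value after rounding both sides
#' to `digits` decimals -- the check that applies to published Malmquist
#' summary tables, which print rounded components.
#'
#' @param records A data frame with columns `unit_id` (or any label),
#'   `effch`, `techch`, `pech`, `sech`, `tfpch`.
#' @param digits Decimal places of the printed table (default 3).
#' @return The input with `tfpch_rebuilt`, `effch_rebuilt`, `tfpch_ok`,
#'   `effch_ok` columns appended.
#' @export
check_decomposition <- function(records, digits = 3) {
  need <- c("effch", "techch", "pech", "sech", "tfpch")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0) {
    stop(sprintf("missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  records |>
    mutate(
      tfpch_rebuilt = round(.data$effch * .data$techch, digits),
      effch_rebuilt = round(.data$pech * .data$sech, digits),
      tfpch_ok = .data$tfpch_rebuilt == round(.data$tfpch, digits),
      effch_ok = .data$effch_rebuilt == round(.data$effch, digits)
    )
}

#' Published province-mean Malmquist components
#'
#' Province-mean Malmquist index components (efficiency change, technical
#' change, pure efficiency change, scale efficiency change, TFP change) for
#' the 31 Chinese provinces over 2014--2018, as printed in a published
#' national health-care efficiency study. Bundled as a worked example for
#' [check_decomposition()] and for comparing table formats; the package does
#' not attempt to re-estimate these values (the underlying yearbook data are
#' not redistributable).
#'
#' @return A tibble: `unit_id`, `effch`, `techch`, `pech`, `sech`, `tfpch`.
#' @export
published_malmquist_means <- function() {
  path <- system.file("extdata", "china_malmquist_means_2014_2018.csv",
                      package = "econet", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(unit_id = readr::col_character(),
                                          .default = readr::col_double()))
}

#' Format a Malmquist summary table for display
#'
#' Rounds components to `digits` decimals, snapping values within `1e-6` of
#' one to exactly 1 first (frontier units print as 1, not 0.999999...).
#'
#' @param means Output of [province_means()].
#' @param digits Decimal places.
#' @return A tibble of formatted numbers.
#' @export
format_malmquist_table <- function(means, digits = 3) {
  snap <- function(x) round(ifelse(abs(x - 1) < 1e-6, 1, x), digits)
  means |>
    mutate(across(c("effch", "techch", "pech", "sech", "tfpch"), snap))
}
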