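#' Per-unit summary for the regional typology
#'
#' Averages the analysis variables (TFP change, indegree, eigenvector
#' centrality, clustering coefficient) across years for each unit. The
#' typology groups units, not unit-years, so clustering operates on these
#' per-unit means.
#'
#' @param apanel An [analysis_panel()] table.
#' @param vars Variables to average.
#' @return A tibble: `unit_id` plus the mean of each variable.
#' @export
unit_summary <- function(apanel,
                         vars = c("tfpch", "indegree", "eigenvector",
                                  "clustering")) {
  apanel |>
    group_by(.data$unit_id) |>
    summarise(across(dplyr::all_of(vars), ~ mean(.x, na.rm = TRUE)),
              .groups = "drop")
}

#' Principal-component features of the analysis variables
#'
#' Standardizes the variables (zero mean, unit sample SD, unless
#' `standardize = FALSE`) and extracts principal components. Component signs
#' are fixed so each component's largest-magnitude loading is positive,
#' making scores reproducible across platforms. The returned object keeps
#' all components (for reconstruction) but reports scores on the top
#' `n_components`.
#'
#' @param df A data frame of one row per unit: an optional `unit_id` column
#'   plus numeric feature columns.
#' @param vars Feature columns (default: every numeric column).
#' @param standardize Scale each variable to unit sample SD before the
#'   decomposition (default `TRUE`).
#' @param n_components Number of leading components to report (default 2).
#' @return An object of class `econet_pca`: `scores` (tibble with the
#'   leading components), `explained` (tibble of per-component variance
#'   ratios and the cumulative share), plus rotation and scaling details.
#' @export
pca_features <- function(df, vars = NULL, standardize = TRUE,
                         n_components = 2) {
  unit_id <- if ("unit_id" %in% names(df)) df$unit_id else
    sprintf("U%02d", seq_len(nrow(df)))
  vars <- vars %||% names(df)[vapply(df, is.numeric, logical(1))]
  if (nrow(df) < 3) stop("need at least 3 units", call. = FALSE)
  X <- as.matrix(df[, vars, drop = FALSE])
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    stop(sprintf("zero-variance variable(s): %s",
                 paste(vars[sds == 0], collapse = ", ")), call. = FALSE)
  }
  pc <- prcomp(X, center = TRUE, scale. = standardize)
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(pc$rotation))) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) {
      pc$rotation[, j] <- -load
      pc$x[, j] <- -pc$x[, j]
    }
  }
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(n_components, ncol(pc$x))
  scores <- as_tibble(pc$x[, seq_len(k), drop = FALSE])
  scores <- dplyr::bind_cols(tibble(unit_id = unit_id), scores)
  structure(list(
    scores = scores,
    explained = tibble(component = paste0("PC", seq_along(evr)),
                       ratio = evr, cumulative = cumsum(evr)),
    rotation = pc$rotation, sdev = pc$sdev,
    center = pc$center, scale = pc$scale,
    scores_full = pc$x, vars = vars, n_components = k
  ), class = "econet_pca")
}

#' @export
print.econet_pca <- function(x, ...) {
  cat(sprintf("<econet_pca> %d units, %d variables, %d components reported\n",
              nrow(x$scores), length(x$vars), x$n_components))
  cat(sprintf("  cumulative explained variance (top %d): %.3f\n",
              x$n_components, x$explained$cumulative[x$n_components]))
  invisible(x)
}

#' @export
tidy.econet_pca <- function(x, ...) {
  as_tibble(x$rotation, rownames = "variable") |>
    tidyr::pivot_longer(-"variable", names_to = "component",
                        values_to = "loading")
}

#' @export
glance.econet_pca <- function(x, ...) x$explained

#' Select k by silhouette and cluster the units
#'
#' Runs k-means (with `n_restarts` random initializations per k, best
#' within-cluster sum of squares kept) on the leading PCA scores for every
#' k in `k_range`, reports the within-cluster sum of squares (inertia, the
#' elbow curve) and the mean silhouette width for each k, and keeps the
#' labels of the silhouette-maximizing k (ties broken towards smaller k).
#' Deterministic given `seed`. A best silhouette below 0.5 triggers a
#' low-confidence warning: the chosen k is still reported but the data show
#' weak group separation.
#'
#' @param x An [pca_features()] result, or a data frame / matrix of scores
#'   (an optional `unit_id` column is carried through).
#' @param k_range Candidate numbers of groups, within `[2, n - 1]`.
#' @param n_restarts Random initializations per k.
#' @param seed Integer seed for the initializations.
#' @return An object of class `cluster_result`: `labels` (tibble `unit_id`,
#'   `cluster`), `diagnostics` (tibble `k`, `inertia`, `silhouette`),
#'   `chosen_k`, `scores`, `seed`.
#' @export
select_k_and_cluster <- function(x, k_range = 2:8, n_restarts = 50,
                                 seed = 1L) {
  if (inherits(x, "econet_pca")) {
    scores_tb <- x$scores
  } else {
    scores_tb <- as_tibble(as.data.frame(x))
    if (!"unit_id" %in% names(scores_tb)) {
      scores_tb <- dplyr::bind_cols(
        tibble(unit_id = sprintf("U%02d", seq_len(nrow(scores_tb)))),
        scores_tb)
    }
  }
  S <- as.matrix(scores_tb[, setdiff(names(scores_tb), "unit_id")])
  n <- nrow(S)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2) || any(k_range >= n)) {
    stop(sprintf("k_range must lie within [2, n - 1] = [2, %d]", n - 1),
         call. = FALSE)
  }
  d <- dist(S)
  n_distinct_pts <- nrow(unique(S))
  fits <- withr::with_seed(seed, {
    lapply(k_range, function(k) {
      if (k > n_distinct_pts) return(NULL)
      kmeans(S, centers = k, nstart = n_restarts, iter.max = 100)
    })
  })
  diagnostics <- purrr::map2_dfr(k_range, fits, function(k, fit) {
    if (is.null(fit)) {
      return(tibble(k = k, inertia = NA_real_, silhouette = NA_real_))
    }
    sil <- cluster::silhouette(fit$cluster, d)
    tibble(k = k, inertia = fit$tot.withinss,
           silhouette = mean(sil[, "sil_width"]))
  })
  ok <- which(!is.na(diagnostics$silhouette))
  if (length(ok) == 0) stop("no k produced a valid clustering", call. = FALSE)
  best <- ok[which.max(diagnostics$silhouette[ok])]
  if (diagnostics$silhouette[best] < 0.5) {
    warning(sprintf(
      "weak cluster separation (best mean silhouette %.2f); chosen k = %d is low-confidence",
      diagnostics$silhouette[best], diagnostics$k[best]))
  }
  chosen_k <- diagnostics$k[best]
  labels <- tibble(unit_id = scores_tb$unit_id,
                   cluster = fits[[best]]$cluster)
  structure(list(labels = labels, diagnostics = diagnostics,
                 chosen_k = chosen_k, scores = scores_tb, seed = seed,
                 kmeans = fits[[best]]),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> chosen k = %d (mean silhouette %.3f)\n",
              x$chosen_k,
              x$diagnostics$silhouette[x$diagnostics$k == x$chosen_k]))
  print(dplyr::count(x$labels, .data$cluster))
  invisible(x)
}

#' @export
tidy.cluster_result <- function(x, ...) {
  left_join(x$labels, x$scores, by = "unit_id")
}

#' @export
glance.cluster_result <- function(x, ...) {
  best <- x$diagnostics[x$diagnostics$k == x$chosen_k, ]
  tibble(chosen_k = x$chosen_k, silhouette = best$silhouette,
         inertia = best$inertia, n_units = nrow(x$labels))
}
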