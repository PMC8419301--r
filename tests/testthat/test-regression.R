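small_apanel <- function(seed = 17, ...) {
  sim <- generate_panel(synthetic_config(seed = seed, ...))
  analysis_panel(sim$panel)
}

test_that("descriptives use sample SD and report N per variable", {
  df <- tibble::tibble(a = c(5, 5, 5), b = c(0, 1, 2))
  d <- descriptives(df, vars = c("a", "b"))
  expect_equal(d$sd, c(0, 1))
  expect_equal(d$mean, c(5, 1))
  expect_equal(d$min, c(5, 0))
  expect_equal(d$max, c(5, 2))
  expect_equal(d$n, c(3, 3))
})

test_that("the default analysis panel has 155 rows and complete descriptives", {
  ap <- small_apanel()
  expect_equal(nrow(ap), 155)
  d <- descriptives(ap)
  expect_equal(d$n, rep(155, 4))
  expect_setequal(d$variable,
                  c("tfpch", "indegree", "eigenvector", "clustering"))
})

test_that("alignment flags label transitions by either endpoint", {
  sim <- generate_panel(synthetic_config(n_units = 8, n_years = 3, seed = 3))
  endp <- analysis_panel(sim$panel, align = "end_year")
  startp <- analysis_panel(sim$panel, align = "start_year")
  yrs <- sort(unique(sim$panel$year))
  expect_setequal(unique(endp$year), yrs[-1])
  expect_setequal(unique(startp$year), yrs[-length(yrs)])
  expect_equal(nrow(endp), nrow(startp))
})

test_that("three pooled models share the sample and report adjusted R^2", {
  ap <- small_apanel()
  models <- fit_tfp_models(ap)
  gl <- glance(models)
  expect_equal(gl$n_obs, rep(155, 3))
  expect_true(all(gl$adj.r.squared <= 1))
  td <- tidy(models)
  expect_setequal(unique(td$model), c("indegree", "eigenvector", "clustering"))
  # region and year dummies present, reference categories dropped
  terms_one <- td$term[td$model == "indegree"]
  expect_true(any(grepl("^region", terms_one)))
  expect_true(any(grepl("^year_f", terms_one)))
})

test_that("planted indegree effect is recovered", {
  sim <- generate_panel(synthetic_config(seed = 31, noise_sd = 0.01))
  ap <- analysis_panel(sim$panel)
  fit <- fit_tfp_models(ap)$fits$indegree
  est <- coef(fit)["indegree"]
  ci <- stats::confint(fit)["indegree", ]
  expect_gt(est, 0)
  expect_true(ci[1] <= sim$truth$beta_indegree &&
                sim$truth$beta_indegree <= ci[2])
})

test_that("adding a constant to tfpch moves only the intercept", {
  ap <- small_apanel(seed = 23)
  m1 <- fit_tfp_models(ap)
  ap2 <- dplyr::mutate(ap, tfpch = tfpch + 5)
  m2 <- fit_tfp_models(ap2)
  for (mod in c("indegree", "eigenvector", "clustering")) {
    expect_equal(coef(m2$fits[[mod]])[[mod]], coef(m1$fits[[mod]])[[mod]],
                 tolerance = 1e-8)
    expect_equal(coef(m2$fits[[mod]])[["(Intercept)"]],
                 coef(m1$fits[[mod]])[["(Intercept)"]] + 5,
                 tolerance = 1e-8)
  }
})

test_that("constant response gives zero slopes and a zero adjusted R^2 guard", {
  ap <- small_apanel(seed = 29)
  ap$tfpch <- 1
  models <- fit_tfp_models(ap)
  # summary() warns about the perfect fit; the guard is what is under test
  td <- suppressWarnings(tidy(models))
  slopes <- td$estimate[td$term %in% c("indegree", "eigenvector", "clustering")]
  expect_equal(unname(slopes), rep(0, 3), tolerance = 1e-10)
  expect_equal(suppressWarnings(glance(models))$adj.r.squared, rep(0, 3))
})

test_that("degenerate designs are rejected with informative errors", {
  ap <- small_apanel(seed = 3)
  one_region <- dplyr::mutate(ap, region = "west")
  expect_error(fit_tfp_models(one_region), "regions")
  one_year <- dplyr::filter(ap, year == min(year))
  expect_error(fit_tfp_models(one_year), "years")
  collinear <- dplyr::mutate(ap, indegree = as.numeric(year == 2014) * 2)
  # indegree duplicating a year dummy must be flagged, not silently dropped
  expect_error(fit_tfp_models(collinear), "collinear")
})

test_that("the formatted table carries the journal layout", {
  ap <- small_apanel(seed = 7)
  lines <- format_tfp_table(fit_tfp_models(ap))
  expect_true(any(grepl("^Observations\t155", lines)))
  expect_true(any(grepl("^Region\tControl", lines)))
  expect_true(any(grepl("^Year\tControl", lines)))
  expect_true(any(grepl("^Adj R-squared", lines)))
})
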