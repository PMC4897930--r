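# a fake fit with two draws and fully known parameters, on a 2x2 grid
known_fit <- function() {
  areas <- make_geography(2, 2, seed = 401)
  drawsf <- cbind(
    intercept = c(0, 0.5), cycle2 = c(0, 0.2),
    `age12-19` = c(0, -1), `age20-29` = c(0, 0.3), `age30-39` = c(0, 0.1),
    `age40-49` = c(0, 0.2), `age60-69` = c(0, -0.2), `age70-79` = c(0, -0.8),
    `age80+` = c(0, -1.5)
  )
  u <- matrix(c(0, 0, 0, 0, 0.4, -0.4, 0.1, -0.1), 2, 4, byrow = TRUE)
  v <- matrix(c(0, 0, 0, 0, -0.2, 0.2, 0, 0), 2, 4, byrow = TRUE)
  list(fit = fake_fit(drawsf, u, v, areas, n_cycles = 2), areas = areas)
}

test_that("cell probabilities follow the linear predictor exactly", {
  kf <- known_fit()
  cells <- tibble::tibble(area_id = c("A001", "A002"),
                          cycle = c(1, 2),
                          age_group = c("50-59", "20-29"))
  p <- cell_prevalence_draws(kf$fit, cells)
  # draw 1: all parameters zero -> probability one half
  expect_equal(p[1, ], c(0.5, 0.5))
  # draw 2: direct formula evaluation
  expect_equal(p[2, 1], plogis(0.5 + 0.4 - 0.2))
  expect_equal(p[2, 2], plogis(0.5 + 0.2 + 0.3 - 0.4 + 0.2))
})

test_that("one income-scale unit multiplies the cell odds by exp(gamma)", {
  areas <- make_geography(1, 2, seed = 402)
  gamma <- -0.13
  inc <- c(A001 = 0, A002 = 1)  # one scale unit apart
  fit <- fake_fit(
    cbind(intercept = c(-1, -0.5), income = c(gamma, gamma)),
    u = matrix(0, 2, 2), v = matrix(0, 2, 2), areas = areas,
    spec = model_spec("current_smoking", "M", include_income = TRUE),
    income_centred = inc
  )
  cells <- tibble::tibble(area_id = c("A001", "A002"), cycle = 1,
                          age_group = "50-59")
  p <- cell_prevalence_draws(fit, cells)
  odds <- p / (1 - p)
  expect_equal(odds[, 2] / odds[, 1], rep(exp(gamma), 2), tolerance = 1e-12)
})

test_that("model-2 cells in income-suppressed areas are marked unavailable", {
  kf <- known_fit()
  cells <- tibble::tibble(area_id = c("A001", "GONE"), cycle = 1,
                          age_group = "50-59")
  p <- cell_prevalence_draws(kf$fit, cells)
  expect_false(anyNA(p[, 1]))
  expect_true(all(is.na(p[, 2])))
})

test_that("post-stratification is a census-weighted convex combination", {
  areas <- make_geography(2, 2, seed = 403) |> simulate_census(seed = 404)
  # constant cell probability p per draw: area prevalence must equal p
  fitc <- fake_fit(
    cbind(intercept = qlogis(c(0.2, 0.6))),
    u = matrix(0, 2, 4), v = matrix(0, 2, 4), areas = areas, n_cycles = 1
  )
  ap <- poststratify_area(fitc, areas)
  draws <- attr(ap, "draws")
  expect_equal(unname(draws[1, ]), rep(0.2, 4), tolerance = 1e-12)
  expect_equal(unname(draws[2, ]), rep(0.6, 4), tolerance = 1e-12)
  expect_true(all(ap$ci_low <= ap$posterior_mean &
                    ap$posterior_mean <= ap$ci_high))
})

test_that("two-cell weighted mean and count-scaling invariance hold", {
  # N = (100, 300) at p = (0.1, 0.3) -> 0.25
  expect_equal(weighted.mean(c(0.1, 0.3), c(100, 300)), 0.25)

  kf <- known_fit()
  areas <- simulate_census(kf$areas, seed = 405)
  ap1 <- poststratify_area(kf$fit, areas)
  scaled <- areas
  pop_cols <- grep("^pop_", names(scaled))
  scaled[pop_cols] <- scaled[pop_cols] * 7
  ap2 <- poststratify_area(kf$fit, scaled)
  expect_equal(attr(ap1, "draws"), attr(ap2, "draws"), tolerance = 1e-12)

  zero <- areas
  zero[1, pop_cols] <- 0
  expect_error(poststratify_area(kf$fit, zero), "zero census population")
})

test_that("area prevalence draws match the cell-level oracle", {
  sf <- shared_fit()
  fit <- sf$fit
  areas <- sf$world$areas
  id <- fit$data$graph$area_ids[3]
  K <- fit$data$n_cycles
  cells <- tidyr::expand_grid(area_id = id, cycle = seq_len(K),
                              age_group = age_groups())
  cd <- cell_prevalence_draws(fit, cells)[1:25, ]
  counts <- as.numeric(areas[areas$area_id == id,
                             paste0("pop_M_", age_groups())])
  names(counts) <- age_groups()
  want <- oracle_poststrat(cd, as.list(counts), cells)
  ap <- poststratify_area(fit, areas)
  expect_equal(unname(attr(ap, "draws")[1:25, id]), want, tolerance = 1e-9)
})

test_that("aggregation is population-weighted and internally consistent", {
  kf <- known_fit()
  areas <- simulate_census(kf$areas, seed = 406)
  ap <- poststratify_area(kf$fit, areas)

  # single-area groups reproduce the area summaries
  solo <- areas
  solo$county_id <- solo$area_id
  agg <- aggregate_prevalence(ap, solo, "county")
  expect_equal(agg$estimate[match(ap$area_id, agg$group)],
               ap$posterior_mean, tolerance = 1e-12)

  # equal populations, constant draws 0.2 / 0.4 -> 0.3
  a2 <- make_geography(1, 2, seed = 407) |> simulate_census(seed = 408)
  pop_cols <- grep("^pop_", names(a2))
  a2[2, pop_cols] <- a2[1, pop_cols]
  a2$county_id <- "one"
  f2 <- fake_fit(cbind(intercept = qlogis(c(0.5, 0.5))),
                 u = matrix(rep(c(qlogis(0.2), qlogis(0.4)), 2), 2, 2,
                            byrow = TRUE) - qlogis(0.5),
                 v = matrix(0, 2, 2), areas = a2, n_cycles = 1)
  ap2 <- poststratify_area(f2, a2)
  agg2 <- aggregate_prevalence(ap2, a2, "county")
  expect_equal(agg2$estimate, 0.3, tolerance = 1e-12)

  # region equals the population-weighted combination of its counties
  region <- aggregate_prevalence(ap, areas, "region")
  counties <- aggregate_prevalence(ap, areas, "county")
  expect_equal(
    region$estimate,
    weighted.mean(counties$estimate, counties$population),
    tolerance = 1e-12
  )
})

test_that("credible intervals are nested across coverage levels", {
  sf <- shared_fit()
  draws <- attr(poststratify_area(sf$fit, sf$world$areas), "draws")
  q50 <- apply(draws, 2, quantile, c(0.25, 0.75))
  q95 <- apply(draws, 2, quantile, c(0.025, 0.975))
  expect_true(all(q95[1, ] <= q50[1, ] & q50[2, ] <= q95[2, ]))
  expect_true(all(draws >= 0 & draws <= 1))
})

test_that("design-based estimator matches hand computation", {
  # equal weights reduce to the raw proportion
  resp <- tibble::tibble(
    respondent_id = as.character(1:6), area_id = "A001",
    county_id = c("c1", "c1", "c1", "c2", "c2", "c2"),
    sex = factor("M", levels = c("M", "F")), cycle = 1,
    design_weight = c(10, 20, 30, 10, 10, 20),
    pooled_weight = c(10, 20, 30, 10, 10, 20),
    boot_wt_1 = c(12, 18, 30, 20, 0, 20),
    boot_wt_2 = c(8, 22, 30, 0, 20, 20),
    smoker = c(1L, 0L, 1L, 1L, 0L, 0L)
  )
  db <- design_based_estimate(resp, "current_smoking", "county")
  # hand computation, c1: (10 + 30) / 60; replicates 42/60, 38/60
  expect_equal(db$estimate[db$group == "c1"], 40 / 60)
  reps <- c(42 / 60, 38 / 60)
  expect_equal(db$se[db$group == "c1"],
               sqrt(mean((reps - 40 / 60)^2)))
  # identical replicate estimates give zero variance
  same <- resp
  same$boot_wt_1 <- same$pooled_weight
  same$boot_wt_2 <- same$pooled_weight
  db0 <- design_based_estimate(same, "current_smoking", "county")
  expect_equal(db0$se, c(0, 0))
  expect_error(design_based_estimate(dplyr::select(resp, -pooled_weight),
                                     "current_smoking"),
               "rescale_pooled_weights")
})

test_that("validation flags model estimates outside design intervals", {
  model <- tibble::tibble(group = c("a", "b"), estimate = c(0.25, 0.40))
  design <- tibble::tibble(group = c("a", "b"), estimate = c(0.25, 0.30),
                           ci_low = c(0.20, 0.25), ci_high = c(0.30, 0.35))
  v <- validate_model_vs_design(model, design)
  expect_equal(v$by_group$covered, c(TRUE, FALSE))
  expect_equal(v$coverage, 0.5)
  expect_error(
    validate_model_vs_design(model,
                             dplyr::mutate(design, group = c("a", "zzz"))),
    "different groups"
  )
})
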