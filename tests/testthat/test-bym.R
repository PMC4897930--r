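# small hand-made respondent table (outcome already classified)
tiny_respondents <- function(areas, n_per_area, seed, p = 0.4, K = 2,
                             ages = c(25, 55, 70)) {
  withr::with_seed(seed, {
    n <- n_per_area * nrow(areas)
    tibble::tibble(
      respondent_id = sprintf("r%03d", seq_len(n)),
      area_id = rep(areas$area_id, each = n_per_area),
      sex = factor("M", levels = c("M", "F")),
      age_years = sample(rep(ages, 2), n, replace = TRUE),
      cycle = sample.int(K, n, replace = TRUE),
      design_weight = runif(n, 5, 50),
      smoker = rbinom(n, 1, p)
    ) |>
      dplyr::mutate(age_group = age_group_of(age_years))
  })
}

test_that("model and MCMC configuration objects enforce their contracts", {
  expect_error(model_spec(income_scale = -1), "positive")
  expect_error(mcmc_config(n_chains = 1), "chains")
  expect_error(mcmc_config(thin = 0), "thin")
  expect_error(mcmc_config(n_keep = 5, thin = 2), "multiple")
  expect_equal(n_saved_draws(mcmc_config(3, 100, 200, 2)), 300L)
})

test_that("log posterior matches a respondent-level brute-force oracle", {
  areas <- make_geography(2, 2, "rook", seed = 1)
  resp <- tiny_respondents(areas, 2, seed = 2)  # 4 areas, 8 respondents
  for (fam in c("gamma_precision", "uniform_sd")) {
    spec <- model_spec("current_smoking", "M", prior_family = fam)
    data <- bym_data(resp, areas, spec)
    params <- random_params(areas, colnames(data$X), seed = 3)
    got <- log_posterior(params, data)
    resp$y <- resp$smoker
    want <- oracle_log_posterior(resp, areas, params, spec)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("log posterior is invariant to respondent order", {
  areas <- make_geography(2, 3, seed = 4)
  resp <- tiny_respondents(areas, 4, seed = 5)
  spec <- model_spec("current_smoking", "M")
  params <- random_params(areas, colnames(bym_data(resp, areas, spec)$X),
                          seed = 6)
  lp1 <- log_posterior(params, bym_data(resp, areas, spec))
  perm <- withr::with_seed(7, sample.int(nrow(resp)))
  lp2 <- log_posterior(params, bym_data(resp[perm, ], areas, spec))
  expect_equal(lp1, lp2, tolerance = 1e-12)
})

test_that("ICAR prior depends on u only through pairwise differences", {
  areas <- make_geography(2, 3, seed = 8)
  resp <- tiny_respondents(areas, 3, seed = 9)
  spec <- model_spec("current_smoking", "M")
  data <- bym_data(resp, areas, spec)
  params <- random_params(areas, colnames(data$X), seed = 10)
  shift <- 0.7
  shifted <- params
  shifted$u <- params$u + shift                      # constant shift of u
  shifted$beta["intercept"] <- params$beta[["intercept"]] - shift
  lp_diff <- log_posterior(shifted, data) - log_posterior(params, data)
  # likelihood and ICAR terms cancel exactly; only the intercept's normal
  # prior sees the shift
  b0 <- params$beta[["intercept"]]
  sd0 <- spec$prior_hyperparameters$fixed_effect_sd
  expect_equal(lp_diff, (b0^2 - (b0 - shift)^2) / (2 * sd0^2),
               tolerance = 1e-10)
  # and a constant u vector has zero pairwise-difference energy: shifting
  # a flat field leaves the whole posterior unchanged up to that same term
  flat <- params
  flat$u <- rep(0, length(params$u))
  flat_shift <- flat
  flat_shift$u <- rep(0.3, length(params$u))
  flat_shift$beta["intercept"] <- flat$beta[["intercept"]] - 0.3
  expect_equal(
    log_posterior(flat_shift, data) - log_posterior(flat, data),
    (b0^2 - (b0 - 0.3)^2) / (2 * sd0^2),
    tolerance = 1e-10
  )
})

test_that("fitting is exactly reproducible under a fixed seed", {
  w <- small_world(seed = 201, n_rows = 4, n_cols = 4, sampling_rate = 0.08)
  spec <- model_spec("current_smoking", "F")
  f1 <- suppressMessages(fit_bym(w$respondents, w$areas, spec,
                                 quick_config(seed = 31)))
  f2 <- suppressMessages(fit_bym(w$respondents, w$areas, spec,
                                 quick_config(seed = 31)))
  expect_equal(f1$draws, f2$draws)
  expect_equal(f1$deviance, f2$deviance)
  f3 <- suppressMessages(fit_bym(w$respondents, w$areas, spec,
                                 quick_config(seed = 32)))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("saved draws respect the configured count and the u constraint", {
  w <- small_world(seed = 211, n_rows = 4, n_cols = 4, sampling_rate = 0.08)
  cfg <- quick_config(seed = 33)
  fit <- suppressMessages(fit_bym(w$respondents, w$areas,
                                  model_spec("current_smoking", "M"), cfg))
  expect_equal(nrow(fit$draws), n_saved_draws(cfg))
  u_cols <- grep("^u_", colnames(fit$draws))
  expect_lt(max(abs(rowSums(fit$draws[, u_cols]))), 1e-8)
  expect_true(all(fit$draws[, c("sigma_u", "sigma_v")] > 0))
})

test_that("posterior mean of the intercept matches dense numerical integration", {
  # 2 areas, fixed random-effect scales: the constrained posterior has three
  # effective dimensions (intercept, the spatial contrast w with
  # u = (w, -w), and v integrated per area), tractable by quadrature
  areas <- make_geography(1, 2, seed = 301)
  resp <- tiny_respondents(areas, 20, seed = 302, p = 0.35, K = 1, ages = 55)
  spec <- model_spec("current_smoking", "M")
  data <- bym_data(resp, areas, spec)
  sig_u <- 0.4; sig_v <- 0.3
  y1 <- sum(data$y[data$area == 1]); m1 <- sum(data$m[data$area == 1])
  y2 <- sum(data$y[data$area == 2]); m2 <- sum(data$m[data$area == 2])

  vg <- seq(-4 * sig_v, 4 * sig_v, length.out = 161)
  g_area <- function(t, y, m) {
    # log integral over the iid effect v of binomial(y; m, plogis(t + v))
    vapply(t, function(tt) {
      eta <- tt + vg
      ll <- y * eta - m * log1p(exp(eta)) + stats::dnorm(vg, 0, sig_v,
                                                         log = TRUE)
      mx <- max(ll)
      mx + log(sum(exp(ll - mx)))
    }, 0)
  }
  b0g <- seq(-2.5, 1.5, length.out = 201)
  wg <- seq(-1.6, 1.6, length.out = 201)
  grid <- expand.grid(b0 = b0g, w = wg)
  lp <- g_area(grid$b0 + grid$w, y1, m1) + g_area(grid$b0 - grid$w, y2, m2) +
    # ICAR on u = (w, -w): pairwise difference (2w)^2
    (-0.5 * (2 * grid$w)^2 / sig_u^2) -
    grid$b0^2 / (2 * spec$prior_hyperparameters$fixed_effect_sd^2)
  post <- exp(lp - max(lp))
  b0_oracle <- sum(grid$b0 * post) / sum(post)

  cfg <- mcmc_config(3, 1000, 3000, 3, seed = 303)
  fit <- fit_bym(resp, areas, spec, cfg,
                 fixed_scales = list(sigma_u = sig_u, sigma_v = sig_v))
  b0_mcmc <- mean(fit$draws[, "intercept"])
  expect_equal(b0_mcmc, b0_oracle, tolerance = 0.05)
})

test_that("data simulated without spatial structure shrinks sigma_u", {
  areas <- make_geography(5, 5, seed = 311) |> simulate_census(seed = 312)
  fit_for <- function(su, seed) {
    truth <- ground_truth(areas, sigma_u = su, sigma_v = 0, seed = seed)
    r <- simulate_survey(areas, truth, sampling_rate = 0.15,
                         n_bootstrap = 2, seed = seed + 1)
    suppressMessages(fit_bym(r, areas, model_spec("current_smoking", "M"),
                             quick_config(seed = 35, burn = 600, keep = 600)))
  }
  f0 <- fit_for(0, 313)
  f5 <- fit_for(0.5, 315)
  expect_lt(mean(f0$draws[, "sigma_u"]), mean(f5$draws[, "sigma_u"]))
})

test_that("split R-hat and autocorrelation behave on constructed chains", {
  base <- fake_fit(
    draws_fixed = matrix(0, 40, 1, dimnames = list(NULL, "intercept")),
    u = matrix(0, 40, 4), v = matrix(0, 40, 4),
    areas = make_geography(2, 2, seed = 1)
  )
  base$chain <- rep(1:2, each = 20)
  # constant draws everywhere: R-hat is exactly 1, lag-0 autocorrelation 1
  d <- convergence_diagnostics(base, parameters = "intercept",
                               lags = c(0, 1))
  expect_equal(d$rhat$rhat, 1)
  expect_equal(d$autocorrelation$acf[d$autocorrelation$lag == 0], 1)

  # two well-separated chains: R-hat far above 1.1
  sep <- base
  sep$draws[, "intercept"] <- withr::with_seed(9, {
    c(rnorm(20, 0, 1), rnorm(20, 10, 1))
  })
  d2 <- convergence_diagnostics(sep, parameters = "intercept")
  expect_gt(d2$rhat$rhat, 1.1 * 3)

  single <- base
  single$chain <- rep(1L, 40)
  expect_error(convergence_diagnostics(single), "2 chains")
})

test_that("DIC identity and degenerate-posterior limits hold", {
  w <- small_world(seed = 321, n_rows = 3, n_cols = 3, sampling_rate = 0.08)
  fit <- suppressMessages(fit_bym(w$respondents, w$areas,
                                  model_spec("current_smoking", "M"),
                                  quick_config(seed = 41, burn = 200,
                                               keep = 200)))
  d <- dic(fit)
  expect_equal(d$dic, 2 * d$mean_deviance - d$deviance_at_mean,
               tolerance = 1e-12)

  # degenerate posterior: every draw identical -> pD = 0, DIC = D(theta)
  deg <- fit
  deg$draws <- deg$draws[rep(1, nrow(deg$draws)), ]
  deg$deviance <- rep(deg$deviance[1], length(deg$deviance))
  dd <- dic(deg)
  expect_equal(dd$pD, 0, tolerance = 1e-9)
  expect_equal(dd$dic, dd$deviance_at_mean, tolerance = 1e-9)
})

test_that("per-draw and at-mean deviance match the brute-force oracle", {
  areas <- make_geography(2, 2, seed = 331)
  resp <- tiny_respondents(areas, 3, seed = 332)
  spec <- model_spec("current_smoking", "M")
  fit <- fit_bym(resp, areas, spec, quick_config(seed = 43, burn = 100,
                                                 keep = 100))
  resp$y <- resp$smoker
  ids <- fit$data$graph$area_ids
  for (s in c(1, 50)) {
    params <- list(
      beta = fit$draws[s, colnames(fit$data$X)],
      u = unname(fit$draws[s, paste0("u_", ids)]),
      v = unname(fit$draws[s, paste0("v_", ids)])
    )
    expect_equal(fit$deviance[s], oracle_deviance(resp, areas, params, spec),
                 tolerance = 1e-9)
  }
  d <- dic(fit)
  mean_params <- list(
    beta = colMeans(fit$draws)[colnames(fit$data$X)],
    u = unname(colMeans(fit$draws)[paste0("u_", ids)]),
    v = unname(colMeans(fit$draws)[paste0("v_", ids)])
  )
  expect_equal(d$deviance_at_mean,
               oracle_deviance(resp, areas, mean_params, spec),
               tolerance = 1e-9)
})

test_that("DIC comparison applies the difference-greater-than-7 rule", {
  mk <- function(dic_val, fp = "a|b|1|1") {
    structure(list(mean_deviance = dic_val, deviance_at_mean = dic_val,
                   pD = 0, dic = dic_val, fingerprint = fp),
              class = "dic_result")
  }
  exactly7 <- compare_models_dic(mk(107), mk(100))
  expect_false(exactly7$meaningful)   # strict inequality at 7.0
  expect_equal(exactly7$preferred, "model_b")

  big <- compare_models_dic(mk(192.4), mk(100), labels = c("model 1", "model 2"))
  expect_true(big$meaningful)
  expect_equal(big$preferred, "model 2")
  expect_equal(big$difference, 92.4)

  tie <- compare_models_dic(mk(100), mk(100))
  expect_equal(tie$preferred, "neither")
  expect_error(compare_models_dic(mk(1), mk(2, fp = "other")), "different data")
})

test_that("income-suppressed areas are excluded from model 2 with a message", {
  w <- small_world(seed = 341, n_rows = 4, n_cols = 4, sampling_rate = 0.1)
  w$areas$median_income[c(2, 7)] <- NA
  spec2 <- model_spec("current_smoking", "M", include_income = TRUE)
  msgs <- capture_messages(data <- bym_data(w$respondents, w$areas, spec2))
  expect_true(any(grepl("suppressed", msgs)))
  expect_equal(data$income_dropped_areas, w$areas$area_id[c(2, 7)])
  expect_false(any(w$areas$area_id[c(2, 7)] %in% data$graph$area_ids))
  # model 1 keeps them
  data1 <- suppressMessages(
    bym_data(w$respondents, w$areas, model_spec("current_smoking", "M"))
  )
  expect_length(data1$graph$area_ids, 16)
})

test_that("prior sensitivity report is reproducible and small at this scale", {
  w <- small_world(seed = 351, n_rows = 4, n_cols = 4, sampling_rate = 0.15)
  spec <- model_spec("current_smoking", "M")
  ps1 <- suppressMessages(prior_sensitivity(w$respondents, w$areas, spec,
                                            quick_config(seed = 51)))
  ps2 <- suppressMessages(prior_sensitivity(w$respondents, w$areas, spec,
                                            quick_config(seed = 51)))
  expect_equal(ps1$by_area, ps2$by_area)
  # posterior means agree across hyperprior families relative to posterior sd
  expect_lt(ps1$max_rel_diff, 1)
})

test_that("age-effect estimates track the generating gradient", {
  sf <- shared_fit()
  est <- tidy(sf$fit)
  age_terms <- paste0("age", setdiff(age_groups(), "50-59"))
  truth <- sf$world$truth$age_effects[match(sub("age", "", age_terms),
                                            age_groups())]
  expect_gt(cor(est$estimate[match(age_terms, est$term)], truth,
                method = "spearman"), 0.8)
})
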