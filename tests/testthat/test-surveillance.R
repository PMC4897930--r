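# hand-made area_prevalence with prescribed draws
fake_area_prev <- function(draws, areas, sex = "M") {
  mu <- colMeans(draws)
  out <- tibble::tibble(
    area_id = colnames(draws),
    posterior_mean = mu,
    posterior_sd = apply(draws, 2, sd),
    ci_low = apply(draws, 2, quantile, 0.025),
    ci_high = apply(draws, 2, quantile, 0.975)
  )
  attr(out, "draws") <- draws
  attr(out, "sex") <- sex
  class(out) <- c("area_prevalence", class(out))
  out
}

test_that("exceedance compares each draw to the same-draw regional average", {
  areas <- make_geography(1, 3, seed = 501) |> simulate_census(seed = 502)
  pop <- rowSums(areas[, paste0("pop_M_", age_groups())])
  # area 1 always above the regional mean, area 3 always below
  draws <- cbind(A001 = c(0.9, 0.8, 0.85), A002 = c(0.3, 0.25, 0.2),
                 A003 = c(0.05, 0.1, 0.02))
  ap <- exceedance_probabilities(fake_area_prev(draws, areas), areas)
  expect_equal(ap$exceedance_prob[1], 1)
  expect_true(ap$flagged[1])
  expect_equal(ap$exceedance_prob[3], 0)
  region <- attr(ap, "region_draws")
  expect_equal(region, as.vector(draws %*% pop / sum(pop)))

  # an area identical to the regional average never strictly exceeds it
  one <- make_geography(1, 2, seed = 503) |> simulate_census(seed = 504)
  p2 <- rowSums(one[, paste0("pop_M_", age_groups())])
  same <- cbind(A001 = rep(0.4, 5), A002 = rep(0.4, 5))
  ap2 <- exceedance_probabilities(fake_area_prev(same, one), one)
  expect_equal(ap2$exceedance_prob, c(0, 0))

  # probability exactly 0.95 is flagged ("95 % or more")
  d <- cbind(A001 = c(rep(0.9, 19), 0.1), A002 = c(rep(0.1, 19), 0.9))
  ap3 <- exceedance_probabilities(fake_area_prev(d, one), one)
  expect_equal(ap3$exceedance_prob[1], 0.95)
  expect_true(ap3$flagged[1])
})

test_that("CV classes follow the release-quality thresholds", {
  expect_equal(cv_classify(0.20, 0.02),
               tibble::tibble(cv_percent = 10,
                              cv_class = factor("acceptable",
                                                c("acceptable", "marginal",
                                                  "low"))))
  expect_equal(as.character(cv_classify(1, 0.166)$cv_class), "marginal")
  expect_equal(as.character(cv_classify(1, 0.333)$cv_class), "marginal")
  expect_equal(as.character(cv_classify(1, 0.40)$cv_class), "low")
  expect_equal(as.character(cv_classify(1, 0.1659)$cv_class), "acceptable")
  expect_error(cv_classify(0, 0.1), "non-positive")
})

test_that("precision-exceedance correlation matches the closed form", {
  # perfectly anti-monotone linear pair
  x <- c(0.1, 0.4, 0.6, 0.9)
  expect_equal(precision_exceedance_correlation(x, 1 - x)$r, -1)

  # four-point hand computation
  ex <- c(0.2, 0.5, 0.7, 0.9)
  cv <- c(30, 22, 25, 10)
  got <- precision_exceedance_correlation(ex, cv)
  r_hand <- sum((ex - mean(ex)) * (cv - mean(cv))) /
    sqrt(sum((ex - mean(ex))^2) * sum((cv - mean(cv))^2))
  t_hand <- r_hand * sqrt(2 / (1 - r_hand^2))
  expect_equal(got$r, r_hand, tolerance = 1e-12)
  expect_equal(got$p_value, 2 * stats::pt(-abs(t_hand), df = 2),
               tolerance = 1e-12)

  # independent inputs show no material correlation
  withr::with_seed(61, {
    a <- runif(1000); b <- runif(1000)
  })
  expect_lt(abs(precision_exceedance_correlation(a, b)$r), 0.1)

  expect_error(precision_exceedance_correlation(c(1, 1, 1), c(1, 2, 3)),
               "constant")
  expect_error(precision_exceedance_correlation(1:2, 1:2), "3")
})

test_that("trend test requires the integer-cycle model and strict exclusion", {
  areas <- make_geography(2, 2, seed = 511)
  mk <- function(slope_draws) {
    fake_fit(cbind(intercept = rep(0, length(slope_draws)),
                   cycle_trend = slope_draws),
             u = matrix(0, length(slope_draws), 4),
             v = matrix(0, length(slope_draws), 4),
             areas = areas,
             spec = model_spec("current_smoking", "M",
                               cycle_coding = "integer_trend"))
  }
  # interval strictly inside the positives
  tt <- trend_test(mk(seq(0.1, 0.5, length.out = 100)))
  expect_true(tt$significant)
  expect_gt(tt$slope, 0)
  # interval touching zero at an endpoint is not significant
  tt0 <- trend_test(mk(c(0, 0, seq(0.01, 1, length.out = 39))))
  expect_equal(tt0$ci_low, 0)
  expect_false(tt0$significant)

  cat_fit <- fake_fit(cbind(intercept = rep(0, 4), cycle2 = rep(0, 4)),
                      u = matrix(0, 4, 4), v = matrix(0, 4, 4), areas = areas)
  expect_error(trend_test(cat_fit), "integer_trend")
})

test_that("generated cycle trends are recovered with correct sign", {
  areas <- make_geography(5, 5, seed = 521) |> simulate_census(seed = 522)
  run <- function(trend, seed) {
    cyc <- trend * (0:4)
    truth <- ground_truth(areas, cycle_effects = cyc, sigma_u = 0,
                          sigma_v = 0, seed = seed)
    r <- simulate_survey(areas, truth, sampling_rate = 0.12,
                         n_bootstrap = 2, seed = seed + 1)
    fit <- suppressMessages(fit_bym(
      r, areas,
      model_spec("current_smoking", "M", cycle_coding = "integer_trend"),
      quick_config(seed = seed + 2, burn = 600, keep = 600)
    ))
    trend_test(fit)
  }
  up <- run(0.25, 523)
  expect_true(up$significant)
  expect_gt(up$slope, 0)
  # a zero generating slope should usually not be called significant
  flat <- vapply(1:5, function(s) run(0, 600 + 10 * s)$significant, NA)
  expect_lte(sum(flat), 1)
})

test_that("exceedance flags recover an implanted cluster end to end", {
  areas <- make_geography(7, 7, seed = 531) |> simulate_census(seed = 532)
  truth <- ground_truth(areas, sigma_u = 0, sigma_v = 0, seed = 533)
  resp <- simulate_survey(areas, truth, sampling_rate = 0.08,
                          n_bootstrap = 2, seed = 534)
  targets <- c("A025", areas$neighbours[[25]][1:3])
  resp <- implant_cluster(resp, targets, odds_multiplier = 3, seed = 535)
  fit <- suppressMessages(fit_bym(resp, areas,
                                  model_spec("current_smoking", "M"),
                                  quick_config(seed = 536, burn = 800,
                                               keep = 800)))
  ap <- poststratify_area(fit, areas) |>
    exceedance_probabilities(areas)
  inside <- ap$area_id %in% targets
  expect_gt(mean(ap$exceedance_prob[inside]),
            mean(ap$exceedance_prob[!inside]))
  # flags and CV correlate negatively when a real cluster is present
  ct <- precision_exceedance_correlation(ap$exceedance_prob, ap$cv_percent)
  expect_lt(ct$r, 0)
})
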