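# Census population of the fit's sex per area (12+ coverage), as a named
# vector aligned with `ids`.
.sex_population <- function(areas, sex, ids, by_age = FALSE) {
  cols <- paste0("pop_", sex, "_", .mp_age_groups)
  if (!all(cols %in% names(areas))) {
    abort("`areas` lacks census counts; run simulate_census() first.")
  }
  rows <- match(ids, areas$area_id)
  if (anyNA(rows)) abort("Census table does not cover all model areas.")
  m <- as.matrix(areas[rows, cols])
  dimnames(m) <- list(ids, .mp_age_groups)
  if (by_age) m else setNames(rowSums(m), ids)
}

#' Per-draw cell probabilities from a fitted model
#'
#' For each requested (area, cycle, age band) cell — sex is fixed by the
#' fit's stratum — computes the per-draw probability
#' `plogis(intercept + cycle + age + income + u + v)`. Cells in areas the
#' model could not estimate (income suppressed under model 2) come back as
#' `NA` columns, marked unavailable rather than silently dropped.
#'
#' @param fit A `bym_fit`.
#' @param cells Tibble with `area_id`, `cycle`, `age_group`.
#' @return Matrix with one row per saved draw and one column per cell.
#' @export
cell_prevalence_draws <- function(fit, cells) {
  if (!inherits(fit, "bym_fit")) abort("`fit` must be a bym_fit.")
  draws <- fit$draws
  spec <- fit$spec
  ids <- fit$data$graph$area_ids
  terms <- colnames(fit$data$X)  # the model's own design decides the terms
  out <- matrix(NA_real_, nrow(draws), nrow(cells))
  for (i in seq_len(nrow(cells))) {
    j <- cells$area_id[i]
    if (!j %in% ids) next  # unavailable area (e.g. income-suppressed)
    eta <- draws[, "intercept"]
    k <- cells$cycle[i]
    if (spec$cycle_coding == "categorical") {
      if (k > 1 && paste0("cycle", k) %in% terms) {
        eta <- eta + draws[, paste0("cycle", k)]
      }
    } else {
      eta <- eta + draws[, "cycle_trend"] * (k - 1)
    }
    a <- as.character(cells$age_group[i])
    if (a != .mp_age_ref && paste0("age", a) %in% terms) {
      eta <- eta + draws[, paste0("age", a)]
    }
    if (isTRUE(spec$include_income) && "income" %in% terms) {
      eta <- eta + draws[, "income"] * fit$data$income_centred[[j]]
    }
    eta <- eta + draws[, paste0("u_", j)] + draws[, paste0("v_", j)]
    out[, i] <- plogis(eta)
  }
  out
}

# per-draw area prevalence for one area: census-weighted mean over age bands
# of the cycle-averaged cell probabilities
.area_draws_one <- function(fit, area_id, counts, cycle_w) {
  K <- fit$data$n_cycles
  cells <- tidyr::expand_grid(area_id = area_id, cycle = seq_len(K),
                              age_group = .mp_age_groups)
  p <- cell_prevalence_draws(fit, cells)  # draws x (K*8)
  cyc <- matrix(0, nrow(p), 8)
  for (a in seq_len(8)) {
    idx <- which(cells$age_group == .mp_age_groups[a])
    cyc[, a] <- p[, idx, drop = FALSE] %*% cycle_w
  }
  drop(cyc %*% counts) / sum(counts)
}

#' Post-stratify posterior draws to micro-area prevalence
#'
#' Converts model draws into per-area prevalence: cell probabilities are
#' averaged over cycles (equal weights by default, or each cycle's share of
#' the pooled sample), then weighted by the census age-band counts of the
#' fit's sex and aggregated, all within each draw, so every summary reflects
#' the area's population structure. Per-area posterior mean, sd, 95%
#' credible interval and the coefficient of variation with its precision
#' class are reported.
#'
#' @param fit A `bym_fit`.
#' @param areas Areas tibble with census counts.
#' @param cycle_weights `"equal"` (default) or `"sample_share"`.
#' @return An `area_prevalence` tibble: `area_id`, `posterior_mean`,
#'   `posterior_sd`, `ci_low`, `ci_high`, `cv_percent`, `cv_class`; the
#'   per-draw area prevalence matrix rides along as attribute `"draws"`.
#' @export
poststratify_area <- function(fit, areas,
                              cycle_weights = c("equal", "sample_share")) {
  cycle_weights <- match.arg(cycle_weights)
  if (!inherits(fit, "bym_fit")) abort("`fit` must be a bym_fit.")
  ids <- fit$data$graph$area_ids
  counts <- .sex_population(areas, fit$spec$sex, ids, by_age = TRUE)
  if (any(rowSums(counts) <= 0)) {
    abort("Area(s) with zero census population cannot be post-stratified.")
  }
  K <- fit$data$n_cycles
  cycle_w <- if (cycle_weights == "equal") {
    rep(1 / K, K)
  } else {
    tab <- vapply(seq_len(K),
                  function(k) sum(fit$data$m[fit$data$cells$cycle == k]), 0)
    tab / sum(tab)
  }
  draws <- vapply(ids,
                  function(j) .area_draws_one(fit, j, counts[j, ], cycle_w),
                  numeric(nrow(fit$draws)))
  ci <- apply(draws, 2, quantile, c(0.025, 0.975))
  mu <- unname(colMeans(draws))
  s <- unname(apply(draws, 2, sd))
  cv <- cv_classify(mu, s)
  out <- tibble(
    area_id = ids,
    posterior_mean = mu, posterior_sd = s,
    ci_low = unname(ci[1, ]), ci_high = unname(ci[2, ]),
    cv_percent = cv$cv_percent, cv_class = cv$cv_class
  )
  attr(out, "draws") <- draws
  attr(out, "sex") <- fit$spec$sex
  attr(out, "outcome") <- fit$spec$outcome
  class(out) <- c("area_prevalence", class(out))
  out
}

#' Aggregate area prevalence draws to counties or the whole region
#'
#' Population-weighted combination of the per-draw area prevalences within
#' each group (census populations of the fit's sex as weights), summarised
#' by posterior mean and 95% credible interval.
#'
#' @param area_prev An `area_prevalence` object from [poststratify_area()].
#' @param areas Areas tibble (for `county_id` and census counts).
#' @param grouping `"county"` or `"region"` (the whole study area).
#' @return Tibble `group`, `estimate`, `ci_low`, `ci_high`, `population`,
#'   with the per-draw group prevalences as attribute `"draws"`.
#' @export
aggregate_prevalence <- function(area_prev, areas,
                                 grouping = c("county", "region")) {
  grouping <- match.arg(grouping)
  draws <- attr(area_prev, "draws")
  if (is.null(draws)) abort("`area_prev` must come from poststratify_area().")
  ids <- area_prev$area_id
  pop <- .sex_population(areas, attr(area_prev, "sex"), ids)
  grp <- if (grouping == "region") {
    rep("region", length(ids))
  } else {
    areas$county_id[match(ids, areas$area_id)]
  }
  groups <- sort(unique(grp))
  gd <- vapply(groups, function(g) {
    sel <- grp == g
    if (!any(sel)) abort("Empty group.")
    drop(draws[, sel, drop = FALSE] %*% pop[sel]) / sum(pop[sel])
  }, numeric(nrow(draws)))
  ci <- apply(gd, 2, quantile, c(0.025, 0.975))
  out <- tibble(
    group = groups,
    estimate = unname(colMeans(gd)),
    ci_low = unname(ci[1, ]), ci_high = unname(ci[2, ]),
    population = vapply(groups, function(g) sum(pop[grp == g]), 0,
                        USE.NAMES = FALSE)
  )
  attr(out, "draws") <- gd
  out
}

#' Design-based prevalence with bootstrap-replicate variance
#'
#' The direct survey estimate: within each group, the pooled-weight weighted
#' proportion of the outcome; its variance is the mean squared deviation of
#' the bootstrap replicate-weight estimates around the point estimate, and
#' the 95% confidence interval uses the normal approximation.
#'
#' @param respondents Respondent tibble with `pooled_weight` and `boot_wt_*`
#'   columns (run [rescale_pooled_weights()] first).
#' @param outcome `"current_smoking"` or `"excess_bodyweight"`.
#' @param grouping `"county"` or `"region"`.
#' @param sex Optional `"M"`/`"F"` filter.
#' @return Tibble `group`, `estimate`, `se`, `ci_low`, `ci_high`, `n`.
#' @export
design_based_estimate <- function(respondents,
                                  outcome = c("current_smoking",
                                              "excess_bodyweight"),
                                  grouping = c("county", "region"),
                                  sex = NULL) {
  outcome <- match.arg(outcome)
  grouping <- match.arg(grouping)
  if (!"pooled_weight" %in% names(respondents)) {
    abort("Run rescale_pooled_weights() before design_based_estimate().")
  }
  bw_cols <- grep("^boot_wt_", names(respondents), value = TRUE)
  if (length(bw_cols) == 0) abort("Bootstrap replicate weights are missing.")
  if (!is.null(sex)) respondents <- respondents[respondents$sex == sex, ]
  y <- .outcome_vector(respondents, outcome)
  keep <- !is.na(y)
  respondents <- respondents[keep, , drop = FALSE]
  y <- y[keep]
  grp <- if (grouping == "region") rep("region", nrow(respondents))
         else respondents$county_id
  purrr::map_dfr(sort(unique(grp)), function(g) {
    sel <- grp == g
    w <- respondents$pooled_weight[sel]
    if (sum(w) <= 0) abort(paste0("Group ", g, " has zero weight."))
    est <- sum(w * y[sel]) / sum(w)
    reps <- vapply(bw_cols, function(b) {
      wb <- respondents[[b]][sel]
      if (sum(wb) <= 0) return(NA_real_)
      sum(wb * y[sel]) / sum(wb)
    }, 0)
    reps <- reps[!is.na(reps)]
    v <- mean((reps - est)^2)
    tibble(group = g, estimate = est, se = sqrt(v),
           ci_low = est - qnorm(0.975) * sqrt(v),
           ci_high = est + qnorm(0.975) * sqrt(v),
           n = sum(sel))
  })
}

#' Check model-based estimates against design-based confidence intervals
#'
#' Per group, the model posterior mean is covered when it lies inside the
#' design-based 95% confidence interval; the overall coverage fraction
#' summarises agreement between the two estimation routes.
#'
#' @param model Tibble from [aggregate_prevalence()] (`group`, `estimate`).
#' @param design Tibble from [design_based_estimate()] (`group`, `ci_low`,
#'   `ci_high`).
#' @return List: `by_group` tibble with a `covered` flag and `coverage`
#'   fraction.
#' @export
validate_model_vs_design <- function(model, design) {
  if (!setequal(model$group, design$group)) {
    abort("Model and design summaries cover different groups.")
  }
  d <- design[match(model$group, design$group), ]
  by_group <- tibble(
    group = model$group,
    model_estimate = model$estimate,
    design_estimate = d$estimate,
    design_ci_low = d$ci_low, design_ci_high = d$ci_high,
    covered = model$estimate >= d$ci_low & model$estimate <= d$ci_high
  )
  list(by_group = by_group, coverage = mean(by_group$covered))
}
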