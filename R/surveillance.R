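#' Posterior exceedance probabilities and high-prevalence flags
#'
#' For each area, the fraction of posterior draws in which its
#' post-stratified prevalence strictly exceeds the regional average
#' prevalence *of the same draw* (the regional average is the census
#' population-weighted mean over areas, so regional uncertainty propagates
#' into the comparison). Areas with exceedance probability of 0.95 or more
#' are flagged as elevated.
#'
#' @param area_prev An `area_prevalence` object from [poststratify_area()].
#' @param areas Areas tibble (census counts weight the regional average).
#' @param threshold Flagging threshold on the exceedance probability
#'   (default 0.95; flagged when `>=`).
#' @return `area_prev` with `exceedance_prob` and `flagged` columns added;
#'   the per-draw regional average is attached as attribute
#'   `"region_draws"`.
#' @export
exceedance_probabilities <- function(area_prev, areas, threshold = 0.95) {
  draws <- attr(area_prev, "draws")
  if (is.null(draws)) abort("`area_prev` must come from poststratify_area().")
  ids <- area_prev$area_id
  pop <- .sex_population(areas, attr(area_prev, "sex"), ids)
  region <- drop(draws %*% pop) / sum(pop)
  prob <- colMeans(draws > region)
  area_prev$exceedance_prob <- unname(prob)
  area_prev$flagged <- area_prev$exceedance_prob >= threshold
  attr(area_prev, "region_draws") <- region
  area_prev
}

#' Coefficient of variation and precision class
#'
#' `cv_percent = 100 * sd / mean`; classified against the release thresholds
#' for survey estimates: below 16.6% acceptable, 16.6-33.3% (inclusive)
#' marginal, above 33.3% low precision.
#'
#' @param posterior_mean,posterior_sd Numeric vectors; means must be > 0.
#' @return Tibble `cv_percent`, `cv_class` (factor: acceptable, marginal,
#'   low).
#' @export
#' @examples
#' cv_classify(0.20, 0.02)  # 10%, acceptable
cv_classify <- function(posterior_mean, posterior_sd) {
  if (any(posterior_mean <= 0)) {
    abort("CV is undefined for non-positive means.")
  }
  if (any(posterior_sd < 0)) abort("Standard deviations must be >= 0.")
  cv <- 100 * posterior_sd / posterior_mean
  # classify on a lightly rounded value so the printed thresholds behave
  # exactly at the boundary (100 * 0.333 must read as 33.3, not 33.3 + eps)
  cv_r <- round(cv, 9)
  cls <- dplyr::case_when(
    cv_r < 16.6 ~ "acceptable",
    cv_r <= 33.3 ~ "marginal",
    .default = "low"
  )
  tibble(cv_percent = cv,
         cv_class = factor(cls, levels = c("acceptable", "marginal", "low")))
}

#' Correlation between precision and elevated-prevalence evidence
#'
#' Pearson correlation (with the usual two-sided t-test p-value) between the
#' per-area posterior exceedance probabilities and the coefficients of
#' variation. On real surveillance output this correlation is negative:
#' precisely estimated areas are the ones that can accumulate strong
#' evidence of exceeding the regional average.
#'
#' @param exceedance_probs,cvs Paired numeric vectors (>= 3 pairs, both with
#'   positive variance).
#' @return List: `r`, `p_value`, `n`.
#' @export
precision_exceedance_correlation <- function(exceedance_probs, cvs) {
  if (length(exceedance_probs) != length(cvs)) {
    abort("Input vectors must be paired (equal length).")
  }
  if (length(cvs) < 3) abort("Need at least 3 paired values.")
  if (var(exceedance_probs) == 0 || var(cvs) == 0) {
    abort("Correlation is undefined for a constant input vector.")
  }
  ct <- stats::cor.test(exceedance_probs, cvs, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(cvs))
}

#' Posterior trend test over survey cycles
#'
#' For a model fitted with cycle as an integer covariate, summarises the
#' posterior of the per-cycle slope; the trend is called significant when
#' the central 95% credible interval strictly excludes zero.
#'
#' @param fit A `bym_fit` with `spec$cycle_coding == "integer_trend"`.
#' @return List: `slope` (posterior mean), `ci_low`, `ci_high`,
#'   `significant`.
#' @export
trend_test <- function(fit) {
  if (!inherits(fit, "bym_fit")) abort("`fit` must be a bym_fit.")
  if (fit$spec$cycle_coding != "integer_trend") {
    abort("Fit uses categorical cycles; refit with cycle_coding = \"integer_trend\".")
  }
  s <- fit$draws[, "cycle_trend"]
  ci <- unname(quantile(s, c(0.025, 0.975)))
  list(slope = mean(s), ci_low = ci[1], ci_high = ci[2],
       significant = ci[1] > 0 || ci[2] < 0)
}
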