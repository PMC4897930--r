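#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a BYM fit
#'
#' One row per parameter with posterior mean, sd and central 95% credible
#' interval, plus the odds-ratio scale for fixed effects. Area random
#' effects are omitted unless `include_random = TRUE`.
#'
#' @param x A `bym_fit`.
#' @param include_random Include per-area `u_*` / `v_*` terms?
#' @param ... Unused.
#' @return Tibble: `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`, `odds.ratio` (`NA` for scale parameters).
#' @export
tidy.bym_fit <- function(x, include_random = FALSE, ...) {
  keep <- c(colnames(x$data$X), "sigma_u", "sigma_v")
  if (include_random) keep <- colnames(x$draws)
  d <- x$draws[, keep, drop = FALSE]
  ci <- apply(d, 2, quantile, c(0.025, 0.975))
  fixed <- keep %in% colnames(x$data$X)
  est <- unname(colMeans(d))
  tibble(
    term = keep,
    estimate = est,
    std.error = unname(apply(d, 2, sd)),
    conf.low = unname(ci[1, ]), conf.high = unname(ci[2, ]),
    odds.ratio = ifelse(fixed, exp(est), NA_real_)
  )
}

#' Glance at a BYM fit
#'
#' @param x A `bym_fit`.
#' @param ... Unused.
#' @return One-row tibble: areas, respondents, chains, saved draws, DIC
#'   components, max split R-hat over fixed effects and scales.
#' @export
glance.bym_fit <- function(x, ...) {
  d <- dic(x)
  diag <- convergence_diagnostics(x)
  tibble(
    n_areas = length(x$data$graph$area_ids),
    n_respondents = sum(x$data$m),
    n_chains = x$config$n_chains,
    n_draws = nrow(x$draws),
    dic = d$dic, p_d = d$pD, mean_deviance = d$mean_deviance,
    max_rhat = max(diag$rhat$rhat)
  )
}

#' @export
tidy.moran_test <- function(x, ...) {
  tibble(statistic = x$I, p.value = x$p_value, n_sim = x$n_sim,
         family = x$family)
}

#' @export
glance.moran_test <- function(x, ...) tidy(x)

#' @export
tidy.scan_result <- function(x, ...) {
  dplyr::select(x$clusters, -"member_ids")
}

#' @export
glance.scan_result <- function(x, ...) {
  tibble(n_clusters = nrow(x$clusters),
         best_llr = x$clusters$llr[1],
         best_p = x$clusters$p_value[1],
         n_mc = x$n_mc, total_cases = x$total_cases, total_n = x$total_n)
}

#' @export
tidy.dic_result <- function(x, ...) {
  tibble(mean_deviance = x$mean_deviance,
         deviance_at_mean = x$deviance_at_mean,
         p_d = x$pD, dic = x$dic)
}

#' @export
tidy.area_prevalence <- function(x, ...) {
  out <- x
  attr(out, "draws") <- NULL
  attr(out, "region_draws") <- NULL
  class(out) <- class(tibble())
  out
}
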