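#' Specify a sex-stratified BYM prevalence model
#'
#' Model 1 controls for survey cycle and age band; model 2 additionally
#' includes micro-area median household income (`include_income = TRUE`),
#' centred at the study mean and scaled per `income_scale` dollars so its
#' coefficient is a log-odds ratio per $10,000 by default. Cycle can enter
#' as a categorical effect (reference cycle 1) or as an integer trend.
#'
#' @param outcome `"current_smoking"` or `"excess_bodyweight"`.
#' @param sex `"M"` or `"F"`; models are fitted separately by sex.
#' @param include_income Include the area income covariate (model 2)?
#' @param cycle_coding `"categorical"` (default) or `"integer_trend"`.
#' @param prior_family `"gamma_precision"` (gamma hyperpriors on the random
#'   effect precisions, default) or `"uniform_sd"` (uniform hyperpriors on
#'   the standard deviations).
#' @param prior_hyperparameters Named list: `gamma_shape` (0.5),
#'   `gamma_rate` (0.0005), `unif_upper` (10), `fixed_effect_sd` (10).
#' @param income_scale Dollars per unit of the income covariate (default
#'   10000).
#' @return A `model_spec` object.
#' @export
model_spec <- function(outcome = c("current_smoking", "excess_bodyweight"),
                       sex = c("M", "F"),
                       include_income = FALSE,
                       cycle_coding = c("categorical", "integer_trend"),
                       prior_family = c("gamma_precision", "uniform_sd"),
                       prior_hyperparameters = list(),
                       income_scale = 10000) {
  outcome <- match.arg(outcome)
  sex <- match.arg(sex)
  cycle_coding <- match.arg(cycle_coding)
  prior_family <- match.arg(prior_family)
  if (income_scale <= 0) abort("`income_scale` must be positive.")
  hyper <- utils::modifyList(
    list(gamma_shape = 0.5, gamma_rate = 0.0005, unif_upper = 10,
         fixed_effect_sd = 10),
    prior_hyperparameters
  )
  structure(
    list(outcome = outcome, sex = sex, include_income = include_income,
         cycle_coding = cycle_coding, prior_family = prior_family,
         prior_hyperparameters = hyper, income_scale = income_scale),
    class = "model_spec"
  )
}

#' MCMC run configuration
#'
#' @param n_chains Number of chains (>= 2 so convergence diagnostics work).
#' @param burn_in Iterations discarded per chain.
#' @param n_keep Post-burn-in iterations per chain.
#' @param thin Save every `thin`-th kept iteration; total saved draws are
#'   `n_chains * n_keep / thin`.
#' @param seed Integer seed controlling all chains.
#' @return An `mcmc_config` object.
#' @seealso [mcmc_preset()] for the two named protocols.
#' @export
mcmc_config <- function(n_chains = 3, burn_in = 2000, n_keep = 2000,
                        thin = 2, seed = 1) {
  if (n_chains < 2) abort("`n_chains` must be >= 2 (diagnostics need them).")
  if (thin < 1) abort("`thin` must be >= 1.")
  if (burn_in < 0 || n_keep < thin) abort("Invalid burn-in / kept iterations.")
  if (n_keep %% thin != 0) abort("`n_keep` must be a multiple of `thin`.")
  structure(list(n_chains = as.integer(n_chains),
                 burn_in = as.integer(burn_in),
                 n_keep = as.integer(n_keep), thin = as.integer(thin),
                 seed = seed),
            class = "mcmc_config")
}

#' Named MCMC protocols
#'
#' `"paper"` is the full surveillance protocol: 3 chains, 500,000 burn-in,
#' 50,000 further iterations with every 10th saved, i.e. 5,000 draws per
#' chain and 15,000 in total. `"desk"` is the package default for interactive
#' and test use: 3 chains, 2,000 burn-in, 2,000 kept, thin 2 (3,000 draws).
#'
#' @param name `"desk"` or `"paper"`.
#' @param seed Integer seed.
#' @return An `mcmc_config` object.
#' @export
#' @examples
#' cfg <- mcmc_preset("paper")
#' n_saved_draws(cfg)  # 15000
mcmc_preset <- function(name = c("desk", "paper"), seed = 1) {
  name <- match.arg(name)
  switch(name,
    desk = mcmc_config(3, 2000, 2000, 2, seed),
    paper = mcmc_config(3, 500000, 50000, 10, seed)
  )
}

#' Total saved draws implied by an MCMC configuration
#' @param config An `mcmc_config` object.
#' @return Integer: `n_chains * n_keep / thin`.
#' @export
n_saved_draws <- function(config) {
  as.integer(config$n_chains * (config$n_keep / config$thin))
}

# ---------------------------------------------------------------------------
# data preparation

.log1pexp <- function(x) {
  out <- x
  lo <- x < 35
  out[lo] <- log1p(exp(x[lo]))
  out
}

.icar_quadratic <- function(u, graph) {
  q <- 0
  for (j in seq_along(graph$nb)) {
    for (k in graph$nb[[j]]) if (k > j) q <- q + (u[j] - u[k])^2
  }
  q
}

.n_components <- function(graph) {
  n <- length(graph$area_ids)
  seen <- logical(n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comp <- comp + 1L
    queue <- s
    seen[s] <- TRUE
    while (length(queue) > 0) {
      j <- queue[[1]]; queue <- queue[-1]
      new <- graph$nb[[j]][!seen[graph$nb[[j]]]]
      seen[new] <- TRUE
      queue <- c(queue, new)
    }
  }
  comp
}

#' Prepare model data for BYM fitting
#'
#' Filters to the requested sex, derives and drops missing outcomes (counts
#' reported), removes island areas, optionally drops areas with suppressed
#' income (model 2), and aggregates respondents to binomial
#' area-cycle-age cells, which carry the full likelihood of the individual
#' Bernoulli outcomes.
#'
#' @param respondents Respondent tibble.
#' @param areas Areas tibble (with `median_income` when
#'   `spec$include_income`).
#' @param spec A [model_spec()].
#' @return A `bym_data` object used by [fit_bym()], [log_posterior()] and
#'   [dic()].
#' @export
bym_data <- function(respondents, areas, spec) {
  .check_areas(areas, "neighbours")
  if (!inherits(spec, "model_spec")) abort("`spec` must come from model_spec().")
  resp <- respondents[respondents$sex == spec$sex, , drop = FALSE]
  y <- .outcome_vector(resp, spec$outcome)
  n_missing <- sum(is.na(y))
  if (n_missing > 0) {
    inform(paste0("Dropping ", n_missing,
                  " respondent(s) with missing/excluded outcome."))
  }
  resp <- resp[!is.na(y), , drop = FALSE]
  y <- y[!is.na(y)]
  fingerprint <- paste(spec$outcome, spec$sex, nrow(resp), sum(y), sep = "|")

  income_dropped <- character()
  if (isTRUE(spec$include_income)) {
    if (!"median_income" %in% names(areas)) {
      abort("`include_income = TRUE` but `areas` has no `median_income`.")
    }
    income_dropped <- areas$area_id[is.na(areas$median_income)]
    if (length(income_dropped) > 0) {
      inform(paste0("Income suppressed for ", length(income_dropped),
                    " area(s); excluded from model-2 estimation."))
      areas <- areas[!is.na(areas$median_income), , drop = FALSE]
      areas$neighbours <- lapply(areas$neighbours, intersect, areas$area_id)
    }
  }
  graph <- build_adjacency(areas)
  keep_ids <- graph$area_ids
  in_graph <- resp$area_id %in% keep_ids
  if (!all(in_graph)) {
    inform(paste0("Dropping ", sum(!in_graph),
                  " respondent(s) in excluded areas."))
    resp <- resp[in_graph, , drop = FALSE]
    y <- y[in_graph]
  }
  if (nrow(resp) == 0) abort("No respondents left after filtering.")

  n_cycles <- max(resp$cycle)
  cells <- tibble(area_id = resp$area_id, cycle = resp$cycle,
                  age_group = as.character(resp$age_group), y = y) |>
    dplyr::summarise(y = sum(.data$y), m = dplyr::n(),
                     .by = c("area_id", "cycle", "age_group")) |>
    dplyr::arrange(.data$area_id, .data$cycle, .data$age_group)

  # design matrix: intercept, cycle (categorical ref 1 / integer trend),
  # age bands (ref 50-59), optional centred income per income_scale
  nc <- nrow(cells)
  X <- matrix(1, nc, 1, dimnames = list(NULL, "intercept"))
  if (spec$cycle_coding == "categorical") {
    if (n_cycles > 1) {
      for (k in 2:n_cycles) {
        X <- cbind(X, as.numeric(cells$cycle == k))
        colnames(X)[ncol(X)] <- paste0("cycle", k)
      }
    }
  } else {
    X <- cbind(X, cells$cycle - 1)
    colnames(X)[ncol(X)] <- "cycle_trend"
  }
  for (a in setdiff(.mp_age_groups, .mp_age_ref)) {
    X <- cbind(X, as.numeric(cells$age_group == a))
    colnames(X)[ncol(X)] <- paste0("age", a)
  }
  income_centred <- NULL
  if (isTRUE(spec$include_income)) {
    inc <- areas$median_income[match(keep_ids, areas$area_id)]
    if (any(!is.finite(inc))) abort("Non-finite income covariate.")
    income_centred <- setNames((inc - mean(inc)) / spec$income_scale, keep_ids)
    X <- cbind(X, unname(income_centred[cells$area_id]))
    colnames(X)[ncol(X)] <- "income"
  }
  if (any(!is.finite(X))) abort("Non-finite covariate in design matrix.")

  structure(
    list(X = X, y = cells$y, m = cells$m, cells = cells,
         area = match(cells$area_id, keep_ids),
         graph = graph, n_comp = .n_components(graph),
         n_cycles = n_cycles, income_centred = income_centred,
         income_dropped_areas = income_dropped,
         spec = spec, fingerprint = fingerprint,
         n_missing_outcome = n_missing),
    class = "bym_data"
  )
}

#' Log posterior density of the BYM model
#'
#' Evaluates, up to an additive constant, the log posterior the sampler
#' targets: the binomial cell log-likelihood, the ICAR pairwise-difference
#' log-prior on `u` (with exponent `(n - c)/2` on the precision, `c` the
#' number of graph components), the iid normal log-prior on `v`, independent
#' normal priors on the fixed effects, and the hyperprior — expressed on the
#' precisions `1/sigma^2` for `prior_family = "gamma_precision"` and on the
#' standard deviations for `"uniform_sd"`.
#'
#' @param params List with `beta` (named as `colnames(data$X)`), `u`, `v`
#'   (length = number of areas), `sigma_u`, `sigma_v` (> 0).
#' @param data A [bym_data()] object.
#' @return Scalar log density.
#' @export
log_posterior <- function(params, data) {
  if (!inherits(data, "bym_data")) abort("`data` must come from bym_data().")
  beta <- params$beta; u <- params$u; v <- params$v
  su <- params$sigma_u; sv <- params$sigma_v
  n <- length(data$graph$area_ids)
  if (length(beta) != ncol(data$X) || length(u) != n || length(v) != n) {
    abort("Parameter dimensions do not match the data.")
  }
  if (su <= 0 || sv <= 0) abort("Scales must be positive.")
  eta <- drop(data$X %*% beta) + u[data$area] + v[data$area]
  ll <- sum(data$y * eta - data$m * .log1pexp(eta))
  tau_u <- 1 / su^2; tau_v <- 1 / sv^2
  icar <- 0.5 * (n - data$n_comp) * log(tau_u) -
    0.5 * tau_u * .icar_quadratic(u, data$graph)
  vpr <- 0.5 * n * log(tau_v) - 0.5 * tau_v * sum(v^2)
  fe_sd <- data$spec$prior_hyperparameters$fixed_effect_sd
  fe <- -sum(beta^2) / (2 * fe_sd^2)
  hp <- data$spec$prior_hyperparameters
  hyper <- if (data$spec$prior_family == "gamma_precision") {
    (hp$gamma_shape - 1) * (log(tau_u) + log(tau_v)) -
      hp$gamma_rate * (tau_u + tau_v)
  } else {
    if (su >= hp$unif_upper || sv >= hp$unif_upper) -Inf else 0
  }
  ll + icar + vpr + fe + hyper
}

# deviance (-2 x binomial log-likelihood, no combinatorial constant)
.deviance_at <- function(data, beta, u, v) {
  eta <- drop(data$X %*% beta) + u[data$area] + v[data$area]
  -2 * sum(data$y * eta - data$m * .log1pexp(eta))
}

# ---------------------------------------------------------------------------
# fitting

#' Fit the BYM spatial logistic model by MCMC
#'
#' Metropolis-within-Gibbs sampling of the sex-stratified hierarchical
#' logistic model with BYM (ICAR + iid) area random effects. Proposal scales
#' adapt during burn-in only; the spatial effect is recentred to sum to zero
#' every sweep with a compensating intercept shift. Runs are exactly
#' reproducible under a fixed `config$seed`.
#'
#' @param respondents Respondent tibble.
#' @param areas Areas tibble.
#' @param spec A [model_spec()].
#' @param config An [mcmc_config()] or [mcmc_preset()].
#' @param fixed_scales Optional list `list(sigma_u=, sigma_v=)` to hold the
#'   random-effect scales fixed (no hyperparameter updates); used for
#'   sampler-validation runs.
#' @return A `bym_fit` object: `draws` (matrix, one row per saved draw,
#'   labelled columns for fixed effects, `u_*`, `v_*`, `sigma_u`, `sigma_v`),
#'   `deviance` per draw, `chain` index, the `bym_data` used, and acceptance
#'   rates.
#' @export
fit_bym <- function(respondents, areas, spec = model_spec(),
                    config = mcmc_preset("desk"), fixed_scales = NULL) {
  if (!inherits(config, "mcmc_config")) abort("`config` must come from mcmc_config().")
  data <- if (inherits(respondents, "bym_data")) respondents
          else bym_data(respondents, areas, spec)
  spec <- data$spec
  n <- length(data$graph$area_ids)

  # flatten adjacency + per-area cell lists for the C++ core (0-based)
  adj_off <- c(0L, cumsum(lengths(data$graph$nb)))
  adj_idx <- as.integer(unlist(data$graph$nb, use.names = FALSE) - 1L)
  cells_by_area <- split(seq_along(data$area) - 1L,
                         factor(data$area, levels = seq_len(n)))
  cell_off <- c(0L, cumsum(lengths(cells_by_area)))
  cell_idx <- as.integer(unlist(cells_by_area, use.names = FALSE))

  p <- ncol(data$X)
  beta_init <- numeric(p)
  p_bar <- min(max(sum(data$y) / sum(data$m), 0.02), 0.98)
  beta_init[1] <- qlogis(p_bar)
  hp <- spec$prior_hyperparameters

  chain_seeds <- withr::with_seed(config$seed,
                                  sample.int(2147483646L, config$n_chains))
  res <- lapply(seq_len(config$n_chains), function(ch) {
    withr::with_seed(chain_seeds[ch], {
      .bym_chain(
        data$X, as.numeric(data$y), as.numeric(data$m),
        as.integer(data$area - 1L), adj_idx, adj_off, cell_idx, cell_off,
        as.integer(data$n_comp),
        config$burn_in, config$n_keep, config$thin,
        ifelse(spec$prior_family == "gamma_precision", 0L, 1L),
        hp$gamma_shape, hp$gamma_rate, hp$unif_upper, hp$fixed_effect_sd,
        !is.null(fixed_scales),
        fixed_scales$sigma_u %||% 0.5, fixed_scales$sigma_v %||% 0.5,
        beta_init, 0.5, TRUE
      )
    })
  })
  draws <- do.call(rbind, lapply(res, `[[`, "draws"))
  colnames(draws) <- c(colnames(data$X),
                       paste0("u_", data$graph$area_ids),
                       paste0("v_", data$graph$area_ids),
                       "sigma_u", "sigma_v")
  structure(
    list(
      draws = draws,
      deviance = unlist(lapply(res, `[[`, "deviance"), use.names = FALSE),
      chain = rep(seq_len(config$n_chains), each = nrow(res[[1]]$draws)),
      data = data, spec = spec, config = config,
      fixed_scales = fixed_scales,
      accept = c(beta = mean(vapply(res, `[[`, 0, "accept_beta")),
                 u = mean(vapply(res, `[[`, 0, "accept_u")),
                 v = mean(vapply(res, `[[`, 0, "accept_v")))
    ),
    class = "bym_fit"
  )
}

#' @exportS3Method base::print
print.bym_fit <- function(x, ...) {
  cat("BYM fit:", x$spec$outcome, "/", x$spec$sex,
      if (x$spec$include_income) "(model 2: with income)" else "(model 1)",
      "\n")
  cat("  ", length(x$data$graph$area_ids), "areas,", sum(x$data$m),
      "respondents,", nrow(x$draws), "saved draws in",
      x$config$n_chains, "chains\n")
  cat("   acceptance: beta", round(x$accept["beta"], 2),
      "u", round(x$accept["u"], 2), "v", round(x$accept["v"], 2), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# diagnostics and model comparison

#' Convergence diagnostics: split-chain R-hat and autocorrelation
#'
#' Potential scale reduction is computed after splitting each chain in half
#' (so within-chain drift registers as between-chain variance); when all
#' draws of a parameter are identical the statistic is defined as exactly 1.
#' Autocorrelation is averaged over chains at the requested lags.
#'
#' @param fit A `bym_fit` (needs >= 2 chains and >= 10 draws per chain).
#' @param parameters Character vector of parameter names; defaults to the
#'   fixed effects and the two scales.
#' @param lags Integer lags for the autocorrelation table.
#' @return List of two tibbles: `rhat` (`parameter`, `rhat`) and
#'   `autocorrelation` (`parameter`, `lag`, `acf`).
#' @export
convergence_diagnostics <- function(fit, parameters = NULL,
                                    lags = c(1, 5, 10, 20)) {
  if (length(unique(fit$chain)) < 2) {
    abort("Diagnostics need at least 2 chains.")
  }
  if (min(table(fit$chain)) < 10) abort("Need >= 10 draws per chain.")
  if (is.null(parameters)) {
    parameters <- c(colnames(fit$data$X), "sigma_u", "sigma_v")
  }
  draws <- fit$draws[, parameters, drop = FALSE]

  split_rhat <- function(x, chain) {
    pieces <- unlist(lapply(split(x, chain), function(xc) {
      h <- floor(length(xc) / 2)
      list(xc[seq_len(h)], xc[h + seq_len(h)])
    }), recursive = FALSE)
    m <- length(pieces); n_len <- length(pieces[[1]])
    mu <- vapply(pieces, mean, 0)
    w <- mean(vapply(pieces, var, 0))
    b_over_n <- var(mu)
    if (w == 0 && b_over_n == 0) return(1)
    sqrt(((n_len - 1) / n_len * w + b_over_n) / w)
  }
  rhat <- tibble(
    parameter = parameters,
    rhat = vapply(parameters,
                  function(pp) split_rhat(draws[, pp], fit$chain), 0,
                  USE.NAMES = FALSE)
  )
  max_lag <- max(lags)
  ac <- purrr::map_dfr(parameters, function(pp) {
    by_chain <- vapply(split(draws[, pp], fit$chain), function(xc) {
      if (var(xc) == 0) return(c(1, rep(0, max_lag))[lags + 1])
      a <- drop(acf(xc, lag.max = max_lag, plot = FALSE)$acf)
      a[lags + 1]
    }, numeric(length(lags)))
    tibble(parameter = pp, lag = lags,
           acf = rowMeans(matrix(by_chain, nrow = length(lags))))
  })
  list(rhat = rhat, autocorrelation = ac)
}

#' Deviance information criterion
#'
#' `DIC = D_bar + pD` with `D_bar` the posterior mean deviance and
#' `pD = D_bar - D(theta_bar)` the effective number of parameters, where the
#' deviance at the posterior mean plugs in the means of all parameters
#' including the area random effects. Deviance is minus twice the Bernoulli
#' log-likelihood (no combinatorial constant).
#'
#' @param fit A `bym_fit`.
#' @return A `dic_result`: `mean_deviance`, `deviance_at_mean`, `pD`, `dic`.
#' @export
dic <- function(fit) {
  if (!inherits(fit, "bym_fit")) abort("`fit` must be a bym_fit.")
  d_bar <- mean(fit$deviance)
  theta <- colMeans(fit$draws)
  ids <- fit$data$graph$area_ids
  d_hat <- .deviance_at(fit$data,
                        theta[colnames(fit$data$X)],
                        theta[paste0("u_", ids)],
                        theta[paste0("v_", ids)])
  pd <- d_bar - d_hat
  structure(
    list(mean_deviance = d_bar, deviance_at_mean = d_hat,
         pD = pd, dic = d_bar + pd, fingerprint = fit$data$fingerprint),
    class = "dic_result"
  )
}

#' @exportS3Method base::print
print.dic_result <- function(x, ...) {
  cat("DIC:", round(x$dic, 1), " (Dbar", round(x$mean_deviance, 1),
      ", pD", round(x$pD, 1), ")\n")
  invisible(x)
}

#' Compare two models by DIC
#'
#' Lower DIC is preferred; an absolute difference strictly greater than 7 is
#' treated as meaningful. Both results must come from the same outcome, sex
#' stratum and respondent data (checked via a data fingerprint).
#'
#' @param dic_a,dic_b `dic_result` objects.
#' @param labels Length-2 character labels for reporting.
#' @return List: `preferred` (label or `"neither"`), `difference`
#'   (`dic_a - dic_b`), `meaningful` (logical).
#' @export
compare_models_dic <- function(dic_a, dic_b, labels = c("model_a", "model_b")) {
  if (!inherits(dic_a, "dic_result") || !inherits(dic_b, "dic_result")) {
    abort("Both arguments must be dic_result objects.")
  }
  if (dic_a$fingerprint != dic_b$fingerprint) {
    abort("DIC results come from different data; comparison is meaningless.")
  }
  diff <- dic_a$dic - dic_b$dic
  preferred <- if (diff == 0) "neither" else labels[(diff > 0) + 1]
  list(preferred = preferred, difference = diff,
       meaningful = abs(diff) > 7)
}

#' Prior sensitivity of area-level estimates
#'
#' Refits the model under both hyperprior families (gamma on precisions vs
#' uniform on standard deviations), all else equal, and reports how much the
#' area-level posterior means (of the combined random effect `u + v`) move.
#'
#' @param respondents,areas,spec,config As for [fit_bym()]; `spec`'s own
#'   `prior_family` is ignored.
#' @return List: `by_area` tibble (`area_id`, posterior means under each
#'   arm, difference, pooled posterior sd), `max_abs_diff`, and
#'   `max_rel_diff` (max |difference| / posterior sd).
#' @export
prior_sensitivity <- function(respondents, areas, spec,
                              config = mcmc_preset("desk")) {
  arm <- function(fam) {
    s <- spec; s$prior_family <- fam
    fit_bym(respondents, areas, s, config)
  }
  fg <- arm("gamma_precision")
  fu <- arm("uniform_sd")
  ids <- fg$data$graph$area_ids
  re <- function(fit) {
    fit$draws[, paste0("u_", ids), drop = FALSE] +
      fit$draws[, paste0("v_", ids), drop = FALSE]
  }
  rg <- re(fg); ru <- re(fu)
  by_area <- tibble(
    area_id = ids,
    mean_gamma = colMeans(rg),
    mean_uniform = colMeans(ru),
    diff = colMeans(rg) - colMeans(ru),
    posterior_sd = (apply(rg, 2, sd) + apply(ru, 2, sd)) / 2
  )
  list(by_area = by_area,
       max_abs_diff = max(abs(by_area$diff)),
       max_rel_diff = max(abs(by_area$diff) / by_area$posterior_sd))
}
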