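# Independent brute-force oracles. These deliberately re-derive each quantity
# from first principles (loops, dense matrices, respondent-level likelihoods)
# rather than reusing any package internals.

# Moran's I by explicit double loop over the dense weight matrix.
oracle_moran <- function(obs, exp, areas_tbl) {
  ids <- areas_tbl$area_id
  n <- length(ids)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    W[i, match(areas_tbl$neighbours[[i]], ids)] <- 1
  }
  z <- obs - exp
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

# Bernoulli scan LLR as a likelihood ratio of explicit binomial likelihoods.
oracle_llr <- function(c, n, C, N) {
  p_in <- c / n
  p_out <- (C - c) / (N - n)
  p0 <- C / N
  if (n == N || p_in <= p0) return(0)
  lb <- function(k, m, p) {
    if (p <= 0 || p >= 1) {
      if ((p == 0 && k > 0) || (p == 1 && k < m)) return(-Inf)
      return(0)
    }
    k * log(p) + (m - k) * log(1 - p)
  }
  lb(c, n, p_in) + lb(C - c, N - n, p_out) - lb(C, N, p0)
}

# Respondent-level log posterior: Bernoulli likelihood plus every prior term,
# coded directly from the model definition.
oracle_log_posterior <- function(resp_df, areas_tbl, params, spec,
                                 income_centred = NULL, n_comp = 1) {
  ids <- areas_tbl$area_id
  n <- length(ids)
  eta <- params$beta[["intercept"]] +
    vapply(seq_len(nrow(resp_df)), function(i) {
      e <- 0
      k <- resp_df$cycle[i]
      if (spec$cycle_coding == "categorical") {
        if (k > 1) e <- e + params$beta[[paste0("cycle", k)]]
      } else {
        e <- e + params$beta[["cycle_trend"]] * (k - 1)
      }
      a <- as.character(resp_df$age_group[i])
      if (a != "50-59") e <- e + params$beta[[paste0("age", a)]]
      if (!is.null(income_centred)) {
        e <- e + params$beta[["income"]] * income_centred[[resp_df$area_id[i]]]
      }
      j <- match(resp_df$area_id[i], ids)
      e + params$u[j] + params$v[j]
    }, 0)
  p <- 1 / (1 + exp(-eta))
  ll <- sum(stats::dbinom(resp_df$y, 1, p, log = TRUE))

  tau_u <- params$sigma_u^-2
  tau_v <- params$sigma_v^-2
  ssu <- 0
  for (i in seq_len(n)) {
    for (nbid in areas_tbl$neighbours[[i]]) {
      j <- match(nbid, ids)
      if (j > i) ssu <- ssu + (params$u[i] - params$u[j])^2
    }
  }
  icar <- 0.5 * (n - n_comp) * log(tau_u) - 0.5 * tau_u * ssu
  vpr <- 0.5 * n * log(tau_v) - 0.5 * tau_v * sum(params$v^2)
  hp <- spec$prior_hyperparameters
  fe <- -sum(params$beta^2) / (2 * hp$fixed_effect_sd^2)
  hyper <- if (spec$prior_family == "gamma_precision") {
    (hp$gamma_shape - 1) * (log(tau_u) + log(tau_v)) -
      hp$gamma_rate * (tau_u + tau_v)
  } else {
    if (params$sigma_u >= hp$unif_upper || params$sigma_v >= hp$unif_upper) {
      -Inf
    } else 0
  }
  ll + icar + vpr + fe + hyper
}

# Deviance by respondent-level Bernoulli likelihood.
oracle_deviance <- function(resp_df, areas_tbl, params, spec,
                            income_centred = NULL) {
  ids <- areas_tbl$area_id
  eta <- vapply(seq_len(nrow(resp_df)), function(i) {
    e <- params$beta[["intercept"]]
    k <- resp_df$cycle[i]
    if (spec$cycle_coding == "categorical") {
      if (k > 1) e <- e + params$beta[[paste0("cycle", k)]]
    } else {
      e <- e + params$beta[["cycle_trend"]] * (k - 1)
    }
    a <- as.character(resp_df$age_group[i])
    if (a != "50-59") e <- e + params$beta[[paste0("age", a)]]
    if (!is.null(income_centred)) {
      e <- e + params$beta[["income"]] * income_centred[[resp_df$area_id[i]]]
    }
    j <- match(resp_df$area_id[i], ids)
    e + params$u[j] + params$v[j]
  }, 0)
  p <- 1 / (1 + exp(-eta))
  -2 * sum(stats::dbinom(resp_df$y, 1, p, log = TRUE))
}

# Post-stratified area prevalence, draw by draw and cell by cell.
oracle_poststrat <- function(cell_draws, counts_by_age, cycles) {
  S <- nrow(cell_draws)
  out <- numeric(S)
  ages <- names(counts_by_age)
  for (s in seq_len(S)) {
    num <- 0; den <- 0
    for (a in ages) {
      pa <- mean(cell_draws[s, cycles$age_group == a])
      num <- num + counts_by_age[[a]] * pa
      den <- den + counts_by_age[[a]]
    }
    out[s] <- num / den
  }
  out
}

# parameters drawn haphazardly but reproducibly for oracle comparisons
random_params <- function(areas_tbl, terms, seed) {
  withr::with_seed(seed, {
    n <- nrow(areas_tbl)
    u <- rnorm(n, 0, 0.4)
    u <- u - mean(u)
    list(
      beta = stats::setNames(rnorm(length(terms), 0, 0.5), terms),
      u = u, v = rnorm(n, 0, 0.3),
      sigma_u = runif(1, 0.2, 1), sigma_v = runif(1, 0.2, 1)
    )
  })
}
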