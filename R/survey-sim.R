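# Binary adjacency matrix (dense 0/1) from the neighbours list-column.
.nb_matrix <- function(areas) {
  n <- nrow(areas)
  W <- matrix(0, n, n, dimnames = list(areas$area_id, areas$area_id))
  for (i in seq_len(n)) W[i, areas$neighbours[[i]]] <- 1
  if (!isTRUE(all.equal(W, t(W)))) abort("Adjacency is not symmetric.")
  W
}

#' Ground-truth generating parameters for the synthetic survey
#'
#' Collects the generating parameters of the individual-level risk model:
#' a logit-scale intercept, cycle and age-band offsets (reference cycle 1 and
#' band 50-59), an area-income coefficient per $10,000, and BYM random
#' effects per area. The spatial component `u` is drawn from the intrinsic
#' conditional autoregressive (ICAR) prior through the eigen-structure of the
#' graph Laplacian, scaled to `sigma_u` and recentred to sum exactly to zero;
#' `v` is iid normal with scale `sigma_v`.
#'
#' Defaults follow plausible values for current smoking in a pooled five-cycle
#' regional survey: prevalence near 27% in the reference band, modest
#' declining cycle effects, strong age gradient, odds ratio 0.88 per $10,000
#' of area income.
#'
#' @param areas Areas tibble from [make_geography()] (adjacency is needed to
#'   draw the ICAR effects).
#' @param intercept Log-odds at reference levels.
#' @param cycle_effects Log-odds offsets per cycle; first element must be 0.
#' @param age_effects Log-odds offsets for the 8 age bands; fifth (50-59)
#'   must be 0.
#' @param income_coef Log-odds per $10,000 of area median income (centred).
#' @param sigma_u Marginal scale of the ICAR spatial effect (>= 0).
#' @param sigma_v Scale of the iid area effect (>= 0).
#' @param seed Optional integer seed for the random-effect draws.
#' @return Object of class `ground_truth`: a list with the parameters plus
#'   per-area `u` (sums to zero) and `v`, named by `area_id`.
#' @export
ground_truth <- function(areas,
                         intercept = qlogis(0.27),
                         cycle_effects = log(c(1, 0.87, 0.98, 0.84, 0.88)),
                         age_effects = log(c(0.34, 1.29, 1.16, 1.44,
                                             1, 0.60, 0.24, 0.10)),
                         income_coef = log(0.88),
                         sigma_u = 0.35, sigma_v = 0.15,
                         seed = NULL) {
  .check_areas(areas, "neighbours")
  .check_seed(seed)
  if (abs(cycle_effects[1]) > 1e-12) abort("`cycle_effects[1]` (reference cycle) must be 0.")
  if (length(age_effects) != 8 || abs(age_effects[5]) > 1e-12) {
    abort("`age_effects` must have length 8 with the 50-59 (5th) entry 0.")
  }
  if (sigma_u < 0 || sigma_v < 0) abort("`sigma_u` and `sigma_v` must be >= 0.")
  n <- nrow(areas)
  W <- .nb_matrix(areas)
  Q <- diag(rowSums(W)) - W
  uv <- .with_seed(seed, {
    u <- rep(0, n)
    if (sigma_u > 0) {
      eig <- eigen(Q, symmetric = TRUE)
      pos <- eig$values > 1e-8 * max(eig$values)
      # draw from the intrinsic prior on the non-null eigenspace, then scale
      # so the marginal sd of u is sigma_u
      z <- rnorm(sum(pos)) / sqrt(eig$values[pos])
      u <- drop(eig$vectors[, pos, drop = FALSE] %*% z)
      u <- u - mean(u)
      u <- u * (sigma_u / stats::sd(u))
    }
    v <- if (sigma_v > 0) rnorm(n, 0, sigma_v) else rep(0, n)
    list(u = setNames(u, areas$area_id), v = setNames(v, areas$area_id))
  })
  structure(
    list(intercept = intercept, cycle_effects = cycle_effects,
         age_effects = age_effects, income_coef = income_coef,
         sigma_u = sigma_u, sigma_v = sigma_v,
         u = uv$u, v = uv$v),
    class = "ground_truth"
  )
}

#' @exportS3Method base::print
print.ground_truth <- function(x, ...) {
  cat("Ground truth:", length(x$u), "areas,",
      length(x$cycle_effects), "cycles\n")
  cat("  intercept", signif(x$intercept, 3),
      "| income OR/$10k", signif(exp(x$income_coef), 3),
      "| sigma_u", signif(x$sigma_u, 3),
      "| sigma_v", signif(x$sigma_v, 3), "\n")
  invisible(x)
}

# Relative inclusion propensity by age band: older working-age adults answer
# household surveys at higher rates, teenagers and the very old at lower.
.mp_age_inclusion <- c(`12-19` = 0.6, `20-29` = 0.7, `30-39` = 0.9,
                       `40-49` = 1.0, `50-59` = 1.2, `60-69` = 1.3,
                       `70-79` = 1.2, `80+` = 0.8)

.draw_smoking_response <- function(y, missing_rate) {
  n <- length(y)
  resp <- ifelse(
    y == 1,
    ifelse(runif(n) < 0.8, "daily", "occasional"),
    ifelse(runif(n) < 0.35, "former", "never")
  )
  resp[runif(n) < missing_rate] <- "missing"
  resp
}

.draw_bodymetrics <- function(y, sex, age_years, missing_rate,
                              pregnant_fraction) {
  n <- length(y)
  height <- ifelse(sex == "M", rnorm(n, 1.78, 0.07), rnorm(n, 1.64, 0.065))
  # youth heights scale down toward age 12
  juv <- age_years < 18
  height[juv] <- height[juv] * (0.82 + 0.03 * (age_years[juv] - 12))
  cut <- iotf_cutoff(age_years, sex)           # 25 for adults
  bmi <- ifelse(y == 1,
                cut + rgamma(n, shape = 2, scale = 2.5),
                pmax(cut - rgamma(n, shape = 2, scale = 1.8), 15))
  weight <- bmi * height^2
  miss <- runif(n) < missing_rate
  height[miss] <- NA_real_
  weight[miss] <- NA_real_
  preg <- sex == "F" & age_years >= 15 & age_years <= 49 &
    runif(n) < pregnant_fraction / 0.35  # ~pregnant_fraction of all women
  tibble(height_m = height, weight_kg = weight, pregnant_or_lactating = preg)
}

#' Simulate pooled-cycle survey respondents with design and bootstrap weights
#'
#' Draws respondents area by area for each of `n_cycles` survey cycles with
#' unequal inclusion probabilities by age band (so design weights genuinely
#' vary), assigns the binary risk outcome from the ground-truth linear
#' predictor through the inverse logit, writes raw response fields consistent
#' with the outcome (smoking status, or self-reported height/weight with a
#' pregnancy/lactation flag), and attaches Rao-Wu-style with-replacement
#' bootstrap replicate weights generated within cycle.
#'
#' @param areas Areas tibble with census counts and (optionally) income.
#' @param truth A [ground_truth()] object for the same areas.
#' @param n_cycles Number of pooled cycles; must match
#'   `length(truth$cycle_effects)`.
#' @param sampling_rate Expected fraction of each area's population sampled
#'   per cycle (default 0.055, giving roughly 150 pooled respondents per
#'   area of 550 people over 5 cycles).
#' @param n_bootstrap Number of bootstrap replicate weights (default 100).
#' @param outcome `"current_smoking"` or `"excess_bodyweight"`: decides which
#'   raw response fields are written.
#' @param missing_rate Fraction of missing raw responses (default 0.01).
#' @param pregnant_fraction Fraction of women flagged pregnant/lactating
#'   (bodyweight outcome only; default 0.01).
#' @param seed Optional integer seed.
#' @return Tibble of respondents: ids, `area_id`, `county_id`, `sex`,
#'   `age_years`, `age_group`, `cycle`, point coordinates `x`, `y`,
#'   `design_weight`, raw response fields, the generating probability
#'   `p_true`, the latent outcome `y_true`, and `boot_wt_1` ...
#'   `boot_wt_<n_bootstrap>` columns.
#' @export
simulate_survey <- function(areas, truth, n_cycles = 5,
                            sampling_rate = 0.055, n_bootstrap = 100,
                            outcome = c("current_smoking", "excess_bodyweight"),
                            missing_rate = 0.01, pregnant_fraction = 0.01,
                            seed = NULL) {
  outcome <- match.arg(outcome)
  .check_areas(areas, c("x", "y"))
  .check_seed(seed)
  if (!inherits(truth, "ground_truth")) abort("`truth` must come from ground_truth().")
  if (length(truth$u) != nrow(areas)) {
    abort("`truth` was built for a different number of areas.")
  }
  if (n_cycles < 1) abort("`n_cycles` must be >= 1.")
  if (n_cycles != length(truth$cycle_effects)) {
    abort("`n_cycles` must match length(truth$cycle_effects).")
  }
  if (sampling_rate <= 0 || sampling_rate > 1) {
    abort("`sampling_rate` must be in (0, 1].")
  }

  cells <- census_long(areas)
  # normalise the age propensities so the population-average rate equals
  # sampling_rate, then cap cell inclusion at 1
  w_bar <- sum(.mp_age_inclusion * .mp_age_pyramid)
  incl_by_age <- setNames(.mp_age_inclusion / w_bar * sampling_rate,
                          names(.mp_age_inclusion))
  inc <- if ("median_income" %in% names(areas)) areas$median_income
         else rep(NA_real_, nrow(areas))
  inc_c <- (inc - mean(inc, na.rm = TRUE)) / 10000
  inc_c[is.na(inc_c)] <- 0  # suppressed-income areas sit at the centred mean
  inc_c <- setNames(inc_c, areas$area_id)

  res <- .with_seed(seed, {
    cells <- cells[cells$count > 0, ]
    per_cycle <- lapply(seq_len(n_cycles), function(k) {
      pr <- pmin(unname(incl_by_age[as.character(cells$age_group)]), 1)
      m <- rbinom(nrow(cells), cells$count, pr)
      keep <- m > 0
      tibble(
        area_id = rep(cells$area_id[keep], m[keep]),
        sex = rep(cells$sex[keep], m[keep]),
        age_group = rep(cells$age_group[keep], m[keep]),
        cycle = k,
        design_weight = rep(1 / pr[keep], m[keep])
      )
    })
    resp <- dplyr::bind_rows(per_cycle)
    if (nrow(resp) == 0) {
      abort("`sampling_rate` produced zero respondents; increase it.")
    }
    ai <- match(resp$area_id, areas$area_id)
    gi <- as.integer(resp$age_group)
    resp$age_years <- .mp_age_lower[gi] +
      floor(runif(nrow(resp)) *
              (pmin(.mp_age_upper[gi], 94) - .mp_age_lower[gi] + 1))
    resp$x <- areas$x[ai] + runif(nrow(resp), -0.35, 0.35)
    resp$y <- areas$y[ai] + runif(nrow(resp), -0.35, 0.35)
    resp$county_id <- areas$county_id[ai]

    eta <- truth$intercept +
      truth$cycle_effects[resp$cycle] +
      truth$age_effects[gi] +
      truth$income_coef * inc_c[resp$area_id] +
      truth$u[resp$area_id] + truth$v[resp$area_id]
    resp$p_true <- plogis(unname(eta))
    resp$y_true <- rbinom(nrow(resp), 1, resp$p_true)

    if (outcome == "current_smoking") {
      resp$smoking_response <- .draw_smoking_response(resp$y_true, missing_rate)
    } else {
      resp <- dplyr::bind_cols(
        resp, .draw_bodymetrics(resp$y_true, as.character(resp$sex),
                                resp$age_years, missing_rate,
                                pregnant_fraction)
      )
    }
    bw <- .rao_wu_weights(resp$design_weight, resp$cycle, n_bootstrap)
    dplyr::bind_cols(resp, as_tibble(bw))
  })

  res$respondent_id <- sprintf("R%06d", seq_len(nrow(res)))
  dplyr::relocate(res, "respondent_id", "area_id", "county_id", "sex",
                  "age_years", "age_group", "cycle", "x", "y",
                  "design_weight")
}

# Rao-Wu with-replacement bootstrap: within each cycle of size n_c, draw
# n_c - 1 units with replacement; replicate weight = w * (n_c/(n_c-1)) * k_i
# where k_i counts selections. E[replicate weight] = w.
.rao_wu_weights <- function(w, cycle, n_bootstrap) {
  n <- length(w)
  if (n_bootstrap < 1) {
    return(matrix(numeric(0), n, 0))
  }
  out <- matrix(0, n, n_bootstrap,
                dimnames = list(NULL, paste0("boot_wt_", seq_len(n_bootstrap))))
  for (k in unique(cycle)) {
    idx <- which(cycle == k)
    n_c <- length(idx)
    if (n_c < 2) {
      out[idx, ] <- w[idx]  # degenerate cycle: weight carried through
      next
    }
    for (b in seq_len(n_bootstrap)) {
      draws <- tabulate(sample.int(n_c, n_c - 1, replace = TRUE), nbins = n_c)
      out[idx, b] <- w[idx] * (n_c / (n_c - 1)) * draws
    }
  }
  out
}

#' Implant a high-prevalence cluster into simulated respondents
#'
#' Multiplies the generating odds of the outcome by `odds_multiplier` for all
#' respondents in the target areas and redraws their outcomes (and the raw
#' response fields derived from them). Used to create detection fixtures with
#' a known elevated set of areas; respondents outside the targets are
#' untouched.
#'
#' @param respondents Tibble from [simulate_survey()] (needs `p_true`).
#' @param target_area_ids Non-empty character vector of area ids present in
#'   the data.
#' @param odds_multiplier Multiplier on the generating odds; must be > 1.
#' @param seed Optional integer seed.
#' @return The respondents tibble with outcomes redrawn in the target areas
#'   and `p_true` updated there.
#' @export
implant_cluster <- function(respondents, target_area_ids, odds_multiplier,
                            seed = NULL) {
  .check_seed(seed)
  if (length(target_area_ids) == 0) abort("`target_area_ids` must be non-empty.")
  unknown <- setdiff(target_area_ids, unique(respondents$area_id))
  if (length(unknown) > 0) {
    abort(paste0("Unknown area id(s): ", paste(unknown, collapse = ", ")))
  }
  if (!is.numeric(odds_multiplier) || odds_multiplier <= 1) {
    abort("`odds_multiplier` must be > 1 (use the original data for no cluster).")
  }
  hit <- respondents$area_id %in% target_area_ids
  .with_seed(seed, {
    p <- respondents$p_true[hit]
    p_new <- odds_multiplier * p / (1 - p + odds_multiplier * p)
    respondents$p_true[hit] <- p_new
    respondents$y_true[hit] <- rbinom(sum(hit), 1, p_new)
    if ("smoking_response" %in% names(respondents)) {
      keep_missing <- respondents$smoking_response[hit] == "missing"
      new_resp <- .draw_smoking_response(respondents$y_true[hit], 0)
      new_resp[keep_missing] <- "missing"
      respondents$smoking_response[hit] <- new_resp
    } else if ("height_m" %in% names(respondents)) {
      bm <- .draw_bodymetrics(respondents$y_true[hit],
                              as.character(respondents$sex[hit]),
                              respondents$age_years[hit], 0, 0)
      keep_missing <- is.na(respondents$height_m[hit])
      bm$height_m[keep_missing] <- NA_real_
      bm$weight_kg[keep_missing] <- NA_real_
      respondents$height_m[hit] <- bm$height_m
      respondents$weight_kg[hit] <- bm$weight_kg
    }
    respondents
  })
}
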