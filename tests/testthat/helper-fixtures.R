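# Shared fixtures, built in code. Heavier objects are cached for the test
# session so several files can reuse the same fitted model.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# small complete synthetic world: 6x6 grid, census, income, survey
small_world <- function(seed = 42, n_rows = 6, n_cols = 6,
                        sampling_rate = 0.05, n_bootstrap = 8, ...) {
  areas <- make_geography(n_rows, n_cols, "queen", seed = seed) |>
    simulate_census(seed = seed + 1) |>
    simulate_income(seed = seed + 2)
  truth <- ground_truth(areas, seed = seed + 3, ...)
  resp <- simulate_survey(areas, truth, sampling_rate = sampling_rate,
                          n_bootstrap = n_bootstrap, seed = seed + 4)
  list(areas = areas, truth = truth, respondents = resp)
}

quick_config <- function(seed = 7, burn = 400, keep = 400, thin = 2) {
  mcmc_config(n_chains = 2, burn_in = burn, n_keep = keep, thin = thin,
              seed = seed)
}

# one moderately sized fitted model shared across test files
shared_fit <- function() {
  cached("shared_fit", {
    w <- small_world(seed = 101, n_rows = 7, n_cols = 7)
    spec <- model_spec("current_smoking", "M", include_income = TRUE)
    fit <- suppressMessages(
      fit_bym(w$respondents, w$areas, spec, mcmc_preset("desk", seed = 5))
    )
    list(world = w, fit = fit)
  })
}

# assemble a minimal bym_fit-shaped object with prescribed draws, for unit
# tests of post-processing that should not depend on the sampler
fake_fit <- function(draws_fixed, u, v, areas, n_cycles = 2,
                     spec = model_spec("current_smoking", "M"),
                     income_centred = NULL, sigma = NULL) {
  graph <- build_adjacency(areas)
  ids <- graph$area_ids
  S <- nrow(draws_fixed)
  colnames(u) <- paste0("u_", ids)
  colnames(v) <- paste0("v_", ids)
  if (is.null(sigma)) {
    sigma <- matrix(0.5, S, 2, dimnames = list(NULL, c("sigma_u", "sigma_v")))
  }
  draws <- cbind(draws_fixed, u, v, sigma)
  structure(
    list(draws = draws, chain = rep(1L, S),
         spec = spec,
         data = list(X = matrix(0, 0, ncol(draws_fixed),
                                dimnames = list(NULL, colnames(draws_fixed))),
                     graph = graph, n_cycles = n_cycles,
                     income_centred = income_centred,
                     cells = tibble::tibble(cycle = integer()),
                     m = integer())),
    class = "bym_fit"
  )
}

expect_same_tibble <- function(a, b) {
  expect_equal(as.data.frame(a), as.data.frame(b))
}
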