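#' Generate a lattice micro-area geography
#'
#' Builds an `n_rows` by `n_cols` grid of micro areas standing in for census
#' dissemination areas: each area gets a jittered centroid, a symmetric
#' neighbour set under rook or queen contiguity, and a county label (the grid
#' is split into three vertical bands mimicking a region of three contiguous
#' counties, plus the whole study region as their union).
#'
#' @param n_rows,n_cols Grid dimensions; the product must be at least 2.
#' @param adjacency_rule `"queen"` (edges and corners, default) or `"rook"`
#'   (shared edges only).
#' @param n_counties Number of vertical county bands (default 3).
#' @param seed Optional integer seed; same seed gives identical output.
#' @return A tibble with one row per area: `area_id`, `row`, `col`, `x`, `y`
#'   (jittered planar centroid), `county_id`, and `neighbours` (list-column of
#'   neighbouring `area_id`s, symmetric).
#' @export
#' @examples
#' g <- make_geography(3, 3, "queen", seed = 1)
#' lengths(g$neighbours)  # centre area has 8 neighbours, corners 3
make_geography <- function(n_rows, n_cols,
                           adjacency_rule = c("queen", "rook"),
                           n_counties = 3, seed = NULL) {
  adjacency_rule <- match.arg(adjacency_rule)
  .check_seed(seed)
  if (!is.numeric(n_rows) || !is.numeric(n_cols) ||
      n_rows < 1 || n_cols < 1) {
    abort("`n_rows` and `n_cols` must be positive integers.")
  }
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows * n_cols < 2) {
    abort("A 1x1 grid has no possible neighbours; need at least 2 areas.")
  }

  grid <- tidyr::expand_grid(row = seq_len(n_rows), col = seq_len(n_cols))
  n <- nrow(grid)
  id <- sprintf("A%03d", seq_len(n))

  jit <- .with_seed(seed, matrix(runif(2 * n, -0.3, 0.3), ncol = 2))
  county <- pmin(ceiling(grid$col / (n_cols / n_counties)), n_counties)

  # rook: 4-neighbourhood; queen adds diagonals
  steps <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (adjacency_rule == "queen") {
    steps <- rbind(steps, c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
  cell_index <- matrix(NA_integer_, n_rows, n_cols)
  cell_index[cbind(grid$row, grid$col)] <- seq_len(n)
  neighbours <- lapply(seq_len(n), function(i) {
    r <- grid$row[i] + steps[, 1]
    c <- grid$col[i] + steps[, 2]
    keep <- r >= 1 & r <= n_rows & c >= 1 & c <= n_cols
    sort(id[cell_index[cbind(r[keep], c[keep])]])
  })

  tibble(
    area_id = id,
    row = grid$row,
    col = grid$col,
    x = grid$col + jit[, 1],
    y = grid$row + jit[, 2],
    county_id = sprintf("county_%d", county),
    neighbours = neighbours
  )
}

# Census age pyramid: pooled-survey-like age mass, heavier in middle age so
# post-stratification is genuinely non-uniform (weighting bugs then surface).
.mp_age_pyramid <- c(`12-19` = 0.13, `20-29` = 0.12, `30-39` = 0.15,
                     `40-49` = 0.14, `50-59` = 0.15, `60-69` = 0.13,
                     `70-79` = 0.11, `80+` = 0.07)
.mp_sex_split <- c(M = 0.49, F = 0.51)

#' Simulate census age-sex population counts for each area
#'
#' Draws a total population per area around `mean_pop` (Poisson) and splits
#' it over the 16 sex-by-age cells by a fixed age pyramid, mimicking the
#' released census structure of dissemination areas (400-700 residents on
#' average). Counts refer to the surveyed ages (12 and over).
#'
#' @param areas Tibble from [make_geography()].
#' @param mean_pop Mean area population, default 550.
#' @param seed Optional integer seed.
#' @return `areas` with a `population` column and 16 count columns named
#'   `pop_<sex>_<age band>` (e.g. `pop_M_12-19`), all non-negative integers.
#' @export
#' @examples
#' g <- make_geography(4, 4, seed = 1) |> simulate_census(seed = 2)
#' mean(g$population)
simulate_census <- function(areas, mean_pop = 550, seed = NULL) {
  .check_areas(areas)
  .check_seed(seed)
  if (!is.numeric(mean_pop) || length(mean_pop) != 1 || mean_pop <= 0) {
    abort("`mean_pop` must be a single positive number.")
  }
  n <- nrow(areas)
  cell_p <- as.vector(outer(.mp_age_pyramid, .mp_sex_split))  # 16 probs
  cell_names <- as.vector(outer(.mp_age_groups, .mp_sexes,
                                function(a, s) paste0("pop_", s, "_", a)))
  counts <- .with_seed(seed, {
    tot <- rpois(n, mean_pop)
    t(vapply(tot, function(N) as.numeric(stats::rmultinom(1, N, cell_p)),
             numeric(16)))
  })
  colnames(counts) <- cell_names
  out <- dplyr::select(areas, -dplyr::any_of(c("population", cell_names)))
  out$population <- as.integer(rowSums(counts))
  dplyr::bind_cols(out, as_tibble(counts))
}

#' Simulate area median household income, with suppressed areas
#'
#' Median income per area is `base + spatial_gradient * y + noise`, floored
#' at a positive minimum; a fixed fraction of areas get a missing income,
#' emulating census suppression of small-area income tables.
#'
#' @param areas Areas tibble (needs `y` coordinates).
#' @param base Baseline median household income, default 55000.
#' @param spatial_gradient Income change per unit of the `y` coordinate
#'   (currency units), default 500; gives a mild north-south gradient.
#' @param noise_sd Standard deviation of area-level noise, default 8000.
#' @param missing_fraction Fraction of areas with suppressed income in
#'   `[0, 1)`; default 0.015 (16 of 1067 areas in a full-scale region).
#' @param floor Minimum income, default 10000.
#' @param seed Optional integer seed.
#' @return `areas` with a `median_income` column (`NA` where suppressed).
#' @export
simulate_income <- function(areas, base = 55000, spatial_gradient = 500,
                            noise_sd = 8000, missing_fraction = 0.015,
                            floor = 10000, seed = NULL) {
  .check_areas(areas, "y")
  .check_seed(seed)
  if (!is.numeric(missing_fraction) || missing_fraction < 0 ||
      missing_fraction >= 1) {
    abort("`missing_fraction` must be in [0, 1).")
  }
  n <- nrow(areas)
  out <- .with_seed(seed, {
    inc <- pmax(base + spatial_gradient * areas$y + rnorm(n, 0, noise_sd),
                floor)
    n_miss <- base::floor(missing_fraction * n)
    if (n_miss > 0) inc[sample.int(n, n_miss)] <- NA_real_
    inc
  })
  areas$median_income <- out
  areas
}

#' Pivot census counts to one row per area-sex-age cell
#'
#' @param areas Areas tibble with `pop_*` columns from [simulate_census()].
#' @return Tibble with `area_id`, `sex`, `age_group`, `count`.
#' @export
census_long <- function(areas) {
  .check_areas(areas)
  pop_cols <- grep("^pop_[MF]_", names(areas), value = TRUE)
  if (length(pop_cols) != 16) {
    abort("`areas` must carry the 16 `pop_<sex>_<age>` columns; run simulate_census().")
  }
  areas |>
    dplyr::select("area_id", dplyr::all_of(pop_cols)) |>
    tidyr::pivot_longer(-"area_id", names_to = c("sex", "age_group"),
                        names_pattern = "^pop_([MF])_(.+)$",
                        values_to = "count") |>
    dplyr::mutate(
      sex = factor(.data$sex, levels = .mp_sexes),
      age_group = factor(.data$age_group, levels = .mp_age_groups)
    )
}
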