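new_adjacency <- function(area_ids, nb, removed = character(),
                          weights_style = "binary") {
  structure(list(area_ids = area_ids, nb = nb, removed = removed,
                 weights_style = weights_style),
            class = "mp_adjacency")
}

#' @exportS3Method base::print
print.mp_adjacency <- function(x, ...) {
  cat("Adjacency graph:", length(x$area_ids), "areas,",
      sum(lengths(x$nb)) / 2, "edges (", x$weights_style, "weights )\n")
  if (length(x$removed) > 0) {
    cat("  removed islands:", paste(x$removed, collapse = ", "), "\n")
  }
  invisible(x)
}

# Sparse symmetric binary weight matrix for a graph.
.adj_W <- function(graph) {
  n <- length(graph$area_ids)
  i <- rep(seq_len(n), lengths(graph$nb))
  j <- unlist(graph$nb, use.names = FALSE)
  W <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  if (graph$weights_style == "row_standardized") W <- W / Matrix::rowSums(W)
  W
}

#' Build the adjacency graph for a set of micro areas
#'
#' Validates and symmetrizes the neighbour relation, deduplicates edges, and
#' removes island areas (degree zero) the way a disease-mapping analysis
#' must: an area with no neighbours cannot borrow strength from the ICAR
#' term and is excluded (with a message naming it).
#'
#' @param areas Areas tibble with a `neighbours` list-column, or a tibble
#'   with `area_id` plus an `edges` two-column data frame given separately.
#' @param edges Optional data frame of id pairs overriding the `neighbours`
#'   column (duplicates and reversed pairs are collapsed).
#' @param weights_style `"binary"` (default) or `"row_standardized"`;
#'   affects only the weight matrix used by [morans_i()].
#' @return An `mp_adjacency` object: ordered `area_ids`, neighbour index
#'   lists, and the ids of any removed islands.
#' @export
build_adjacency <- function(areas, edges = NULL,
                            weights_style = c("binary", "row_standardized")) {
  weights_style <- match.arg(weights_style)
  .check_areas(areas)
  if (nrow(areas) < 2) abort("Need at least 2 areas.")
  ids <- areas$area_id
  if (is.null(edges)) {
    if (!"neighbours" %in% names(areas)) {
      abort("`areas` needs a `neighbours` list-column (or supply `edges`).")
    }
    edges <- tibble(
      from = rep(ids, lengths(areas$neighbours)),
      to = unlist(areas$neighbours, use.names = FALSE)
    )
  }
  edges <- edges[edges$from != edges$to, , drop = FALSE]  # no self-edges
  bad <- setdiff(c(edges$from, edges$to), ids)
  if (length(bad) > 0) {
    abort(paste0("Edge refers to unknown area id(s): ",
                 paste(unique(bad), collapse = ", ")))
  }
  # symmetrize + dedup via unordered keys
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  key <- !duplicated(paste(a, b))
  a <- a[key]; b <- b[key]

  deg <- table(factor(c(a, b), levels = ids))
  islands <- ids[deg == 0]
  if (length(islands) == nrow(areas)) {
    abort("All areas are isolated; no usable adjacency graph.")
  }
  if (length(islands) > 0) {
    inform(paste0("Removed ", length(islands), " island area(s) with no ",
                  "neighbours: ", paste(islands, collapse = ", ")))
  }
  keep <- setdiff(ids, islands)
  idx <- setNames(seq_along(keep), keep)
  nb <- vector("list", length(keep))
  for (k in seq_along(keep)) nb[[k]] <- integer()
  for (e in seq_along(a)) {
    i <- idx[[a[e]]]; j <- idx[[b[e]]]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  nb <- lapply(nb, sort)
  new_adjacency(keep, nb, removed = islands, weights_style = weights_style)
}

#' Moran's I on residual counts
#'
#' The global autocorrelation statistic on residuals `z = obs - exp` with
#' the graph's spatial weights:
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2`, ranging from about -1
#' (dispersion) to +1 (clustering).
#'
#' @param obs,exp Numeric per-area vectors aligned with `graph$area_ids`.
#' @param graph An `mp_adjacency` object.
#' @return The Moran's I statistic (scalar).
#' @export
morans_i <- function(obs, exp, graph) {
  n <- length(graph$area_ids)
  if (length(obs) != n || length(exp) != n) {
    abort("`obs` and `exp` must match the graph's areas.")
  }
  z <- obs - exp
  if (var(z) == 0) {
    abort("Residuals are constant; Moran's I is undefined.")
  }
  W <- .adj_W(graph)
  s0 <- sum(W)
  (n / s0) * sum(z * as.vector(W %*% z)) / sum(z^2)
}

# Method-of-moments common NB dispersion on observed counts around their
# expectations: excess variance ratio 1/size = sum(z^2 - exp) / sum(exp^2).
.nb_dispersion <- function(obs, exp) {
  z <- obs - exp
  inv_size <- sum(z^2 - exp) / sum(exp^2)
  if (inv_size <= 0) return(Inf)  # under/equi-dispersed: Poisson limit
  1 / inv_size
}

#' Parametric-bootstrap Moran's I test
#'
#' One-tailed test for spatial clustering of observed versus expected area
#' counts. Replicate count vectors are simulated from a negative binomial
#' with mean equal to the expected counts and a common dispersion fitted to
#' the observed counts by the method of moments; when the data are not
#' overdispersed the simulation falls back to Poisson (with a message). The
#' p-value is `(1 + #[I_sim >= I_obs]) / (n_sim + 1)`.
#'
#' @param obs,exp Non-negative per-area counts aligned with the graph.
#' @param graph An `mp_adjacency` object.
#' @param n_sim Number of simulated replicates (default 999).
#' @param seed Optional integer seed.
#' @return A `moran_test` object: `I`, `p_value`, `n_sim`, `observed`,
#'   `expected`, the simulation family used, and the simulated statistics.
#' @export
morans_i_test <- function(obs, exp, graph, n_sim = 999, seed = NULL) {
  .check_seed(seed)
  if (n_sim < 1) abort("`n_sim` must be >= 1.")
  if (any(obs < 0) || any(exp < 0)) abort("Counts must be non-negative.")
  i_obs <- morans_i(obs, exp, graph)
  n <- length(obs)
  size <- .nb_dispersion(obs, exp)
  family <- if (is.finite(size)) "negative_binomial" else "poisson"
  if (family == "poisson") {
    inform("Observed counts are not overdispersed; simulating from Poisson.")
  }
  W <- .adj_W(graph)
  s0 <- sum(W)
  i_sim <- .with_seed(seed, {
    sim <- if (family == "poisson") {
      matrix(rpois(n * n_sim, exp), n, n_sim)
    } else {
      matrix(rnbinom(n * n_sim, mu = exp, size = size), n, n_sim)
    }
    z <- sim - exp
    num <- colSums(z * as.matrix(W %*% z))
    den <- colSums(z^2)
    ok <- den > 0
    (n / s0) * num[ok] / den[ok]
  })
  p <- (1 + sum(i_sim >= i_obs)) / (length(i_sim) + 1)
  structure(
    list(I = i_obs, p_value = p, n_sim = length(i_sim),
         observed = obs, expected = exp, family = family, sims = i_sim),
    class = "moran_test"
  )
}

#' @exportS3Method base::print
print.moran_test <- function(x, ...) {
  cat("Parametric-bootstrap Moran's I (", x$family, " null)\n", sep = "")
  cat("  I =", signif(x$I, 3), " one-tailed p =", signif(x$p_value, 3),
      "(", x$n_sim, "simulations )\n")
  invisible(x)
}

#' Observed and expected area counts for an outcome
#'
#' Aggregates respondents to per-area case counts and pairs them with
#' expected counts under spatial homogeneity: the area respondent total
#' times the overall (study-area mean) proportion, computed within sex when
#' requested. This is the unweighted observed/expected input of the
#' preliminary Moran's I assessment.
#'
#' @param respondents Respondent tibble.
#' @param outcome `"current_smoking"` or `"excess_bodyweight"`.
#' @param sex Optional `"M"`/`"F"` filter.
#' @return Tibble with `area_id`, `n`, `observed`, `expected`.
#' @export
area_counts <- function(respondents,
                        outcome = c("current_smoking", "excess_bodyweight"),
                        sex = NULL) {
  outcome <- match.arg(outcome)
  if (!is.null(sex)) respondents <- respondents[respondents$sex == sex, ]
  y <- .outcome_vector(respondents, outcome)
  keep <- !is.na(y)
  df <- tibble(area_id = respondents$area_id[keep], y = y[keep])
  p_bar <- mean(df$y)
  df |>
    dplyr::summarise(n = dplyr::n(), observed = sum(.data$y),
                     .by = "area_id") |>
    dplyr::mutate(expected = .data$n * p_bar) |>
    dplyr::arrange(.data$area_id)
}

# -- adjacency-list file format: "area_id: n1,n2,n3" one line per area -----

#' Write an adjacency-list file
#'
#' Plain-text format, one line per area: `area_id: neighbour_id,...`.
#'
#' @param x Areas tibble with `neighbours`, or an `mp_adjacency` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(x, path) {
  if (inherits(x, "mp_adjacency")) {
    ids <- x$area_ids
    nbs <- lapply(x$nb, function(j) ids[j])
  } else {
    .check_areas(x, "neighbours")
    ids <- x$area_id
    nbs <- x$neighbours
  }
  lines <- paste0(ids, ": ", vapply(nbs, paste, "", collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read an adjacency-list file
#'
#' @param path File written by [write_adjacency()] (or hand-authored in the
#'   same `id: n1,n2` format). The relation is symmetrized and deduplicated.
#' @return An `mp_adjacency` object.
#' @export
read_adjacency <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, ":", fixed = TRUE)
  ids <- trimws(vapply(parts, `[`, "", 1))
  nbs <- lapply(parts, function(p) {
    if (length(p) < 2 || !nzchar(trimws(p[2]))) return(character())
    trimws(strsplit(p[2], ",", fixed = TRUE)[[1]])
  })
  edges <- tibble(from = rep(ids, lengths(nbs)),
                  to = unlist(nbs, use.names = FALSE))
  build_adjacency(tibble(area_id = ids), edges = edges)
}
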