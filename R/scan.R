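#' Enumerate elliptical scanning windows
#'
#' For every point taken as a centre, every axis ratio and every orientation,
#' grows an ellipse of that shape outward, absorbing points one at a time in
#' order of elliptical distance, and records each nested prefix as a
#' candidate window until the window would exceed the population cap
#' (`max_pop_fraction` of the total population at risk). Ratio 1 gives
#' circular windows. Windows with identical member sets are deduplicated.
#'
#' @param points Tibble with `id`, `x`, `y` and optionally `pop` (population
#'   per point, default 1).
#' @param max_pop_fraction Maximum fraction of the population a window may
#'   hold, in (0, 1]; default 0.10.
#' @param shapes Numeric axis ratios (major/minor); default
#'   `c(1, 1.5, 2, 3, 4, 5)`.
#' @param angles Orientations in degrees; default 12 evenly spaced over
#'   0-180 (ignored for shape 1).
#' @return A `scan_windows` object: `members` (list of point-index vectors),
#'   `meta` tibble (centre, shape, angle, minor semi-axis, size), and the
#'   point table.
#' @export
enumerate_elliptic_windows <- function(points, max_pop_fraction = 0.10,
                                       shapes = c(1, 1.5, 2, 3, 4, 5),
                                       angles = NULL) {
  if (!all(c("x", "y") %in% names(points)) || nrow(points) < 2) {
    abort("`points` needs `x`, `y` columns and at least 2 rows.")
  }
  if (max_pop_fraction <= 0 || max_pop_fraction > 1) {
    abort("`max_pop_fraction` must be in (0, 1].")
  }
  if (is.null(angles)) angles <- seq(0, 180 - 15, by = 15)
  pop <- if ("pop" %in% names(points)) points$pop else rep(1, nrow(points))
  cap <- floor(max_pop_fraction * sum(pop))
  if (cap < 1) abort("Population cap below one point; raise `max_pop_fraction`.")
  n <- nrow(points)

  members <- list()
  meta <- list()
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  for (s in shapes) {
    angs <- if (s == 1) 0 else angles
    for (th in angs) {
      rad <- th * pi / 180
      co <- cos(rad); si <- sin(rad)
      for (i in seq_len(n)) {
        dx <- points$x - points$x[i]
        dy <- points$y - points$y[i]
        # rotate so the major axis lies along the orientation, then shrink it
        d <- sqrt((co * dx + si * dy)^2 / s^2 + (-si * dx + co * dy)^2)
        ord <- order(d, seq_len(n))
        k_max <- findInterval(cap, cumsum(pop[ord]))
        if (k_max < 1) next
        for (k in seq_len(k_max)) {
          mem <- sort(ord[seq_len(k)])
          key <- paste(mem, collapse = ",")
          if (!is.null(seen[[key]])) next
          seen[[key]] <- TRUE
          members[[length(members) + 1]] <- mem
          meta[[length(meta) + 1]] <- c(i, s, th, d[ord[k]], k)
        }
      }
    }
  }
  meta <- do.call(rbind, meta)
  structure(
    list(
      members = members,
      meta = tibble(
        centre_x = points$x[meta[, 1]], centre_y = points$y[meta[, 1]],
        shape = meta[, 2], angle = meta[, 3],
        semi_minor = meta[, 4], size = as.integer(meta[, 5])
      ),
      points = points, cap = cap
    ),
    class = "scan_windows"
  )
}

#' @exportS3Method base::print
print.scan_windows <- function(x, ...) {
  cat("Scan windows:", length(x$members), "unique member sets over",
      nrow(x$points), "points (cap", x$cap, ")\n")
  invisible(x)
}

#' Bernoulli scan log-likelihood ratio
#'
#' The high-rate Bernoulli scan statistic for a window holding `n` of `N`
#' individuals and `c` of `C` cases. Zero when the window rate does not
#' exceed the outside rate (one-sided high scan), when the window is the
#' whole population, or in the null configuration `c/n = C/N`; terms
#' `0 * log(0)` are zero by convention. Vectorised over `c` and `n`.
#'
#' @param c Cases in the window.
#' @param n Individuals in the window.
#' @param C Total cases.
#' @param N Total individuals.
#' @return Non-negative log-likelihood ratio(s).
#' @export
#' @examples
#' bernoulli_llr(2, 2, 2, 4)  # 4 * log(2)
bernoulli_llr <- function(c, n, C, N) {
  if (any(c < 0) || any(c > n) || any(n > N) || C > N || any(c > C)) {
    abort("Need 0 <= c <= n <= N and c <= C <= N.")
  }
  xlx <- function(a, b) ifelse(a > 0, a * log(a / b), 0)
  llr <- xlx(c, n) + xlx(n - c, n) +
    xlx(C - c, N - n) + xlx(N - n - C + c, N - n) -
    xlx(C, N) - xlx(N - C, N)
  llr[n == N | c / n <= C / N] <- 0
  pmax(llr, 0)
}

#' Bernoulli spatial scan test with Monte-Carlo inference
#'
#' Scans the candidate windows for the largest Bernoulli log-likelihood
#' ratio, then assesses it against `n_mc` random permutations of the case
#' labels over all points (the conditional null with the total case count
#' fixed): `p = (1 + #[replicate max >= observed]) / (n_mc + 1)`. Secondary
#' clusters are reported greedily after removing any window overlapping a
#' higher-ranked cluster, each with a p-value against the same replicate-max
#' distribution.
#'
#' @param points Tibble with `id`, `x`, `y` and either a binary `outcome`
#'   column (one row per individual) or `cases` and `n` columns (aggregated
#'   mode: one row per location — e.g. area centroids carrying their
#'   respondents' case and total counts, used when only area-level data
#'   exist). In aggregated mode supply `pop = n` behaviour automatically:
#'   the window cap counts individuals, not locations.
#' @param windows Optional `scan_windows` (enumerated with defaults
#'   otherwise).
#' @param n_mc Number of Monte-Carlo replicates (default 999).
#' @param seed Optional integer seed.
#' @param max_clusters Maximum clusters reported (default 5).
#' @param ... Passed to [enumerate_elliptic_windows()] when `windows` is
#'   NULL.
#' @return A `scan_result`: tibble of ranked clusters (`rank`, centre,
#'   `shape`, `angle`, `cases`, `size`, `llr`, `p_value`, `member_ids`
#'   list-column) with the replicate maxima as attribute `"sim_max"`.
#' @export
scan_test <- function(points, windows = NULL, n_mc = 999, seed = NULL,
                      max_clusters = 5, ...) {
  .check_seed(seed)
  if (n_mc < 1) abort("`n_mc` must be >= 1.")
  aggregated <- all(c("cases", "n") %in% names(points))
  if (aggregated) {
    cases <- as.numeric(points$cases)
    npop <- as.numeric(points$n)
    if (any(cases < 0) || any(cases > npop)) {
      abort("Need 0 <= cases <= n at every location.")
    }
    points$pop <- npop
  } else {
    if (!"outcome" %in% names(points)) {
      abort("`points` needs an `outcome` column (or `cases` and `n`).")
    }
    cases <- as.numeric(points$outcome)
    if (any(!cases %in% c(0, 1))) abort("`outcome` must be binary 0/1.")
    npop <- rep(1, length(cases))
  }
  C <- sum(cases); N <- sum(npop)
  if (C == 0 || C == N) {
    abort("All outcomes identical: scan statistic is undefined.")
  }
  if (is.null(windows)) windows <- enumerate_elliptic_windows(points, ...)
  W <- length(windows$members)
  M <- Matrix::sparseMatrix(
    i = rep(seq_len(W), lengths(windows$members)),
    j = unlist(windows$members, use.names = FALSE),
    x = 1, dims = c(W, nrow(points))
  )
  n_w <- as.vector(M %*% npop)
  c_obs <- as.vector(M %*% cases)
  llr_obs <- bernoulli_llr(c_obs, n_w, C, N)

  sim_max <- .with_seed(seed, {
    # conditional null: permute the C case labels over all N individuals;
    # in aggregated mode that is a multivariate hypergeometric split of the
    # cases over locations
    Y <- if (aggregated) {
      owner <- rep(seq_len(nrow(points)), npop)
      vapply(seq_len(n_mc), function(b) {
        tabulate(owner[sample.int(N, C)], nbins = nrow(points))
      }, numeric(nrow(points)))
    } else {
      vapply(seq_len(n_mc), function(b) cases[sample.int(N)],
             numeric(N))
    }
    cnt <- as.matrix(M %*% Y)
    vapply(seq_len(n_mc),
           function(b) max(bernoulli_llr(cnt[, b], n_w, C, N)), 0)
  })

  # greedy non-overlapping ranking of observed windows
  ord <- order(llr_obs, decreasing = TRUE)
  taken <- integer()
  picked <- integer()
  for (w in ord) {
    if (llr_obs[w] <= 0 || length(picked) >= max_clusters) break
    if (any(windows$members[[w]] %in% taken)) next
    picked <- c(picked, w)
    taken <- c(taken, windows$members[[w]])
  }
  if (length(picked) == 0) picked <- ord[1]  # report the best even if llr 0
  ids <- if ("id" %in% names(points)) points$id else seq_len(nrow(points))
  clusters <- windows$meta[picked, ] |>
    dplyr::mutate(
      rank = dplyr::row_number(),
      semi_major = .data$shape * .data$semi_minor,
      cases = c_obs[picked],
      total = n_w[picked],
      llr = llr_obs[picked],
      p_value = vapply(llr_obs[picked],
                       function(l) (1 + sum(sim_max >= l)) / (n_mc + 1), 0),
      member_ids = lapply(windows$members[picked], function(m) ids[m])
    ) |>
    dplyr::relocate("rank")
  structure(
    list(clusters = clusters, n_mc = n_mc, total_cases = C, total_n = N,
         points = points, sim_max = sim_max),
    class = "scan_result"
  )
}

#' @exportS3Method base::print
print.scan_result <- function(x, ...) {
  cat("Bernoulli spatial scan:", x$total_cases, "cases /", x$total_n,
      "points,", x$n_mc, "Monte-Carlo replicates\n")
  top <- x$clusters[1, ]
  cat("  most likely cluster: size", top$size, "cases", top$cases,
      "LLR", signif(top$llr, 4), "p =", signif(top$p_value, 3), "\n")
  invisible(x)
}
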