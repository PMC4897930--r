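#' Map post-stratified area prevalence
#'
#' Tile map of the per-area posterior mean prevalence on the grid geometry,
#' with flagged areas (when [exceedance_probabilities()] has been run)
#' marked by a point overlay, echoing the hatched-area display conventional
#' in prevalence mapping.
#'
#' @param object An `area_prevalence` object.
#' @param areas Areas tibble (for `row`/`col` coordinates).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.area_prevalence <- function(object, areas, ...) {
  df <- dplyr::left_join(tidy(object),
                         dplyr::select(areas, "area_id", "row", "col"),
                         by = "area_id")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$posterior_mean)) +
    ggplot2::scale_fill_viridis_c(name = "prevalence") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = paste0("Post-stratified prevalence (",
                     attr(object, "outcome"), ", ", attr(object, "sex"), ")"),
      x = NULL, y = NULL
    ) +
    ggplot2::theme_minimal()
  if ("flagged" %in% names(df) && any(df$flagged)) {
    p <- p + ggplot2::geom_point(
      data = df[df$flagged, ],
      shape = 4, size = 2, colour = "white", stroke = 1.2
    )
  }
  p
}

#' Trace plots for a BYM fit
#'
#' @param object A `bym_fit`.
#' @param parameters Parameter names (default: fixed effects and scales).
#' @param ... Unused.
#' @return A ggplot with one facet per parameter, coloured by chain.
#' @export
autoplot.bym_fit <- function(object, parameters = NULL, ...) {
  if (is.null(parameters)) {
    parameters <- c(colnames(object$data$X), "sigma_u", "sigma_v")
  }
  df <- purrr::map_dfr(parameters, function(pp) {
    tibble(parameter = pp, chain = factor(object$chain),
           value = object$draws[, pp]) |>
      dplyr::mutate(iteration = dplyr::row_number(), .by = "chain")
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$value,
                                   colour = .data$chain)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "saved iteration", y = NULL) +
    ggplot2::theme_minimal()
}

#' Null distribution of the bootstrap Moran's I
#'
#' @param object A `moran_test`.
#' @param ... Unused.
#' @return A ggplot: histogram of simulated statistics with the observed
#'   value marked.
#' @export
autoplot.moran_test <- function(object, ...) {
  ggplot2::ggplot(tibble(I = object$sims), ggplot2::aes(.data$I)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$I, colour = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(
      title = sprintf("Moran's I = %.3f, one-tailed p = %.3g (%s null)",
                      object$I, object$p_value, object$family),
      x = "simulated Moran's I", y = "count"
    ) +
    ggplot2::theme_minimal()
}

#' Scan clusters over the point pattern
#'
#' @param object A `scan_result`.
#' @param ... Unused.
#' @return A ggplot: points coloured by outcome, cluster members outlined.
#' @export
autoplot.scan_result <- function(object, ...) {
  pts <- object$points
  if (!"id" %in% names(pts)) pts$id <- seq_len(nrow(pts))
  members <- purrr::map_dfr(seq_len(nrow(object$clusters)), function(k) {
    tibble(id = unlist(object$clusters$member_ids[[k]]),
           cluster = factor(object$clusters$rank[k]))
  })
  df <- dplyr::left_join(pts, members, by = "id")
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$outcome)),
                        size = 1) +
    ggplot2::geom_point(
      data = df[!is.na(df$cluster), ],
      ggplot2::aes(shape = .data$cluster), size = 3, stroke = 0.8,
      colour = "black", fill = NA
    ) +
    ggplot2::scale_colour_manual(values = c(`0` = "grey70", `1` = "firebrick"),
                                 name = "outcome") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
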