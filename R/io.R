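#' Write areas as GeoJSON
#'
#' Emits a FeatureCollection with one feature per area: a unit-cell Polygon
#' when grid `row`/`col` are available (Point otherwise) and properties
#' carrying `area_id`, `county_id`, the mandatory centroid coordinates, and
#' population / median income when present. Neighbour lists are not encoded
#' in GeoJSON; pair the file with [write_adjacency()].
#'
#' @param areas Areas tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geography_geojson <- function(areas, path) {
  .check_areas(areas, c("x", "y"))
  grid <- all(c("row", "col") %in% names(areas))
  features <- lapply(seq_len(nrow(areas)), function(i) {
    props <- list(area_id = areas$area_id[i],
                  centroid_x = areas$x[i], centroid_y = areas$y[i])
    for (extra in c("county_id", "population", "median_income")) {
      if (extra %in% names(areas)) props[[extra]] <- areas[[extra]][i]
    }
    geom <- if (grid) {
      r <- areas$row[i]; c <- areas$col[i]
      ring <- list(c(c - 0.5, r - 0.5), c(c + 0.5, r - 0.5),
                   c(c + 0.5, r + 0.5), c(c - 0.5, r + 0.5),
                   c(c - 0.5, r - 0.5))
      list(type = "Polygon", coordinates = list(ring))
    } else {
      list(type = "Point", coordinates = c(areas$x[i], areas$y[i]))
    }
    list(type = "Feature", properties = props, geometry = geom)
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  )
  invisible(path)
}

#' Read areas back from GeoJSON
#'
#' @param path File written by [write_geography_geojson()] (or compatible:
#'   features with an `area_id` property and centroid coordinates either as
#'   `centroid_x`/`centroid_y` properties or a Point geometry).
#' @return Areas tibble (without neighbour lists; derive adjacency with
#'   [adjacency_from_geojson()] or [read_adjacency()]).
#' @export
read_geography_geojson <- function(path) {
  g <- jsonlite::read_json(path)
  if (!identical(g$type, "FeatureCollection")) abort("Not a FeatureCollection.")
  rows <- purrr::map_dfr(g$features, function(f) {
    p <- f$properties
    x <- p$centroid_x; y <- p$centroid_y
    if (is.null(x) && identical(f$geometry$type, "Point")) {
      x <- f$geometry$coordinates[[1]]; y <- f$geometry$coordinates[[2]]
    }
    tibble(
      area_id = p$area_id, x = as.numeric(x), y = as.numeric(y),
      county_id = p$county_id %||% NA_character_,
      population = as.numeric(p$population %||% NA),
      median_income = as.numeric(p$median_income %||% NA)
    )
  })
  rows
}

#' Queen contiguity from GeoJSON polygons
#'
#' Builds the adjacency graph directly from polygon geometry: two areas are
#' queen-contiguous when their boundary rings share at least one vertex
#' (shared edges therefore also count). Vertices are matched exactly after
#' rounding to `digits` decimals.
#'
#' @param path GeoJSON file with Polygon features carrying an `area_id`
#'   property.
#' @param digits Coordinate rounding used for vertex matching (default 6).
#' @return An `mp_adjacency` object.
#' @export
adjacency_from_geojson <- function(path, digits = 6) {
  g <- jsonlite::read_json(path)
  feats <- g$features
  ids <- vapply(feats, function(f) f$properties$area_id, "")
  verts <- lapply(feats, function(f) {
    if (!identical(f$geometry$type, "Polygon")) {
      abort("Queen contiguity needs Polygon geometry.")
    }
    ring <- f$geometry$coordinates[[1]]
    vapply(ring, function(v) {
      paste(round(as.numeric(v[[1]]), digits),
            round(as.numeric(v[[2]]), digits))
    }, "")
  })
  vert_owner <- split(rep(seq_along(ids), lengths(verts)),
                      unlist(verts, use.names = FALSE))
  pairs <- unique(do.call(rbind, lapply(vert_owner, function(o) {
    o <- unique(o)
    if (length(o) < 2) return(NULL)
    t(utils::combn(sort(o), 2))
  })))
  edges <- tibble(from = ids[pairs[, 1]], to = ids[pairs[, 2]])
  build_adjacency(tibble(area_id = ids), edges = edges)
}

#' Write / read respondent and census tables as CSV
#'
#' Plain readr round-trips with the package's documented column names;
#' factor columns (`sex`, `age_group`) are restored on read.
#'
#' @param respondents,areas Tibbles to write.
#' @param path File path.
#' @return `path` invisibly (writers); a tibble (readers).
#' @name table-io
NULL

#' @rdname table-io
#' @export
write_respondents_csv <- function(respondents, path) {
  readr::write_csv(respondents, path)
  invisible(path)
}

#' @rdname table-io
#' @export
read_respondents_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if ("sex" %in% names(df)) df$sex <- factor(df$sex, levels = .mp_sexes)
  if ("age_group" %in% names(df)) {
    df$age_group <- factor(df$age_group, levels = .mp_age_groups)
  }
  df
}

#' @rdname table-io
#' @export
write_census_csv <- function(areas, path) {
  readr::write_csv(census_long(areas), path)
  invisible(path)
}

#' Write a synthetic-data bundle
#'
#' Convenience writer for a complete synthetic dataset: GeoJSON boundaries,
#' plain adjacency list, respondent and census CSVs, and a JSON sidecar
#' echoing every generation parameter (so a dataset can be described and
#' regenerated).
#'
#' @param dir Output directory (created if needed).
#' @param areas,respondents Generated tibbles.
#' @param params Named list of the generation parameters to echo.
#' @return The directory path, invisibly.
#' @export
write_synthetic_bundle <- function(dir, areas, respondents, params = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_geography_geojson(areas, file.path(dir, "areas.geojson"))
  write_adjacency(areas, file.path(dir, "adjacency.txt"))
  write_census_csv(areas, file.path(dir, "census_cells.csv"))
  write_respondents_csv(respondents, file.path(dir, "respondents.csv"))
  jsonlite::write_json(params, file.path(dir, "generation_params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Persist posterior draws as CSV plus JSON metadata
#'
#' Writes one row per saved draw with labelled columns (`chain`, all model
#' parameters, `deviance`) and a JSON sidecar describing the model
#' specification, the MCMC configuration, and the data fingerprint, so a
#' fit can be archived and reloaded without refitting.
#'
#' @param fit A `bym_fit`.
#' @param path Output CSV path; the metadata goes to `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_bym_draws <- function(fit, path) {
  if (!inherits(fit, "bym_fit")) abort("`fit` must be a bym_fit.")
  df <- dplyr::bind_cols(
    tibble(chain = fit$chain),
    as_tibble(fit$draws),
    tibble(deviance = fit$deviance)
  )
  readr::write_csv(df, path)
  meta <- list(
    spec = unclass(fit$spec),
    config = unclass(fit$config),
    fingerprint = fit$data$fingerprint,
    n_areas = length(fit$data$graph$area_ids),
    n_respondents = sum(fit$data$m),
    accept = as.list(fit$accept)
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read persisted posterior draws
#'
#' @param path CSV written by [write_bym_draws()].
#' @return List with `draws` (matrix), `chain`, `deviance`, and `meta`
#'   (parsed sidecar, `NULL` when absent).
#' @export
read_bym_draws <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  meta_path <- paste0(path, ".meta.json")
  list(
    draws = as.matrix(df[, setdiff(names(df), c("chain", "deviance"))]),
    chain = df$chain,
    deviance = df$deviance,
    meta = if (file.exists(meta_path)) jsonlite::read_json(meta_path)
           else NULL
  )
}
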