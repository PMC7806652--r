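#' Occurrence set
#'
#' A labelled point table: one row per record with projected coordinates
#' (metres) and a label that is either `"presence"` or `"pseudo_absence"`.
#'
#' @param df Data frame with columns `id`, `x`, `y`, `label`.
#' @param crs Free-text CRS tag.
#' @return A data frame of class `occurrence_set`.
#' @export
occurrence_set <- function(df, crs = "local-metres") {
  stopifnot(all(c("id", "x", "y", "label") %in% names(df)))
  if (!all(is.finite(df$x)) || !all(is.finite(df$y)))
    stop("coordinates must be finite")
  if (!all(df$label %in% c("presence", "pseudo_absence")))
    stop("labels must be 'presence' or 'pseudo_absence'")
  structure(df, class = c("occurrence_set", "data.frame"), crs = crs)
}

#' Spatially rarefy presence points
#'
#' Greedy sequential thinning: points are visited in ascending `id` order
#' (or, if `randomize = TRUE`, in a seeded random order) and a point is
#' kept iff no previously kept point lies within `radius` of it
#' (planar Euclidean distance). The retained set is a subset of the input
#' in which no two points are closer than `radius`; re-applying the
#' operation to its own output is a no-op. This reduces spatial
#' autocorrelation among presence records before model fitting (the
#' standard 5 km thinning radius reflects large-carnivore home-range
#' size).
#'
#' @param points An `occurrence_set` of presences only.
#' @param radius Exclusion radius in metres (> 0).
#' @param seed Seed for the randomized order (unused otherwise).
#' @param randomize Visit points in random order instead of by id.
#' @return The thinned `occurrence_set`.
#' @export
spatial_rarefy <- function(points, radius, seed = NULL, randomize = FALSE) {
  if (!is.finite(radius) || radius <= 0) stop("radius must be > 0")
  if (nrow(points) == 0L) return(points)
  if (!all(points$label == "presence"))
    stop("spatial_rarefy expects presence points only")
  ord <- order(points$id)
  if (randomize) ord <- with_seed(seed, sample(ord))
  kept <- integer(0)
  r2 <- radius^2
  for (i in ord) {
    if (length(kept) == 0L ||
        all((points$x[kept] - points$x[i])^2 +
              (points$y[kept] - points$y[i])^2 >= r2))
      kept <- c(kept, i)
  }
  out <- points[sort(kept), , drop = FALSE]
  rownames(out) <- NULL
  occurrence_set(out, crs = attr(points, "crs"))
}

#' Sample pseudo-absence points away from presences
#'
#' Draws `n` points uniformly at random from the non-nodata cells whose
#' centers lie at least `exclusion_radius` from every presence point
#' (the eligible set is computed exactly; cells may be drawn more than
#' once). The pseudo-absences contrast with presence records in the
#' suitability model.
#'
#' @param grid A [grid_spec()], or a [raster_layer()] whose nodata mask
#'   restricts the eligible area.
#' @param presences An `occurrence_set` of presence points.
#' @param exclusion_radius Minimum distance to any presence, metres (>= 0).
#' @param n Number of points (>= 1).
#' @param seed Integer seed.
#' @return An `occurrence_set` labelled `pseudo_absence`.
#' @export
sample_pseudo_absences <- function(grid, presences, exclusion_radius, n, seed) {
  if (n < 1) stop("n must be >= 1")
  if (exclusion_radius < 0) stop("exclusion_radius must be >= 0")
  mask <- NULL
  if (inherits(grid, "raster_layer")) {
    mask <- !is.na(values_rowmajor(grid))
    grid <- grid$grid
  }
  ctr <- cell_centers(grid)
  eligible <- if (is.null(mask)) rep(TRUE, nrow(ctr)) else mask
  if (exclusion_radius > 0 && nrow(presences) > 0) {
    r2 <- exclusion_radius^2
    mind2 <- rep(Inf, nrow(ctr))
    for (i in seq_len(nrow(presences))) {
      d2 <- (ctr$x - presences$x[i])^2 + (ctr$y - presences$y[i])^2
      mind2 <- pmin(mind2, d2)
    }
    eligible <- eligible & (mind2 >= r2)
  }
  idx <- which(eligible)
  if (length(idx) == 0L)
    stop(sprintf(
      "infeasible: no valid cell lies >= %g m from every presence point",
      exclusion_radius))
  ids <- with_seed(seed, sample(idx, n, replace = TRUE))
  pts <- cell_centers(grid, ctr$id[ids])
  occurrence_set(data.frame(id = seq_len(n), x = pts$x, y = pts$y,
                            label = "pseudo_absence"), crs = grid$crs)
}

#' Read and write occurrence points as CSV
#'
#' CSV columns: `id, x, y, label`.
#'
#' @param points An `occurrence_set`.
#' @param path File path.
#' @return `read_points_csv()` returns an `occurrence_set`;
#'   `write_points_csv()` returns `path` invisibly.
#' @export
write_points_csv <- function(points, path) {
  utils::write.csv(as.data.frame(points)[, c("id", "x", "y", "label")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_points_csv
#' @export
read_points_csv <- function(path) {
  occurrence_set(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write points or overlays as GeoJSON
#'
#' Minimal GeoJSON FeatureCollection writers for point sets, polygon sets
#' and polyline sets, in projected map coordinates.
#'
#' @param points An `occurrence_set`.
#' @param polygons A `polygon_set` (list of closed rings).
#' @param lines A `polyline_set` (list of coordinate data frames).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_points_geojson <- function(points, path) {
  feats <- lapply(seq_len(nrow(points)), function(i) list(
    type = "Feature",
    properties = list(id = points$id[i], label = points$label[i]),
    geometry = list(type = "Point",
                    coordinates = c(points$x[i], points$y[i]))))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_points_geojson
#' @export
write_polygons_geojson <- function(polygons, path) {
  feats <- lapply(seq_along(polygons), function(i) list(
    type = "Feature", properties = list(id = i),
    geometry = list(type = "Polygon",
                    coordinates = list(unname(as.matrix(polygons[[i]]))))))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_points_geojson
#' @export
write_polylines_geojson <- function(lines, path) {
  feats <- lapply(seq_along(lines), function(i) list(
    type = "Feature", properties = list(id = i),
    geometry = list(type = "LineString",
                    coordinates = unname(as.matrix(lines[[i]])))))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
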