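## 8-connected component labelling of a logical matrix, via graph
## components over the foreground adjacency.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(t(mask))  # row-major ids of foreground cells
  lab <- matrix(NA_real_, nr, nc)
  if (length(fg) == 0L) return(lab)
  idx <- integer(nr * nc); idx[fg] <- seq_along(fg)  # id -> vertex
  idm <- matrix(seq_len(nr * nc), nr, nc, byrow = TRUE)
  m <- mask; m[is.na(m)] <- FALSE
  edges <- list(); e <- 0L
  for (o in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    dr <- o[1]; dc <- o[2]
    r1 <- seq_len(nr - dr); c1 <- if (dc >= 0) seq_len(nc - dc) else (1 - dc):nc
    if (length(r1) == 0L || length(c1) == 0L) next
    r2 <- r1 + dr; c2 <- c1 + dc
    ok <- m[r1, c1, drop = FALSE] & m[r2, c2, drop = FALSE]
    if (!any(ok)) next
    e <- e + 1L
    edges[[e]] <- rbind(idx[idm[r1, c1, drop = FALSE][ok]],
                        idx[idm[r2, c2, drop = FALSE][ok]])
  }
  el <- if (e > 0L) as.vector(do.call(cbind, edges)) else integer(0)
  gr <- igraph::add_edges(igraph::make_empty_graph(length(fg),
                                                   directed = FALSE), el)
  comp <- igraph::components(gr)$membership
  ## relabel so patch 1 is the largest, ties by first appearance
  sizes <- tabulate(comp)
  ord <- order(-sizes, seq_along(sizes))
  relab <- integer(length(sizes)); relab[ord] <- seq_along(ord)
  labv <- rep(NA_real_, nr * nc)
  labv[fg] <- relab[comp]
  matrix(labv, nr, nc, byrow = TRUE)
}

#' Delineate core habitat patches from a kernel surface
#'
#' Thresholds the cumulative resistant-kernel surface and labels the
#' 8-connected components of the resulting mask as core patches. The
#' default rule keeps cells with kernel value strictly greater than
#' `rel_threshold` times the landscape maximum (fraction-of-maximum); a
#' percentile mode is available, keeping cells above the
#' `rel_threshold` quantile of the positive kernel values.
#'
#' @param kernel A `kernel_surface` (or a non-negative [raster_layer()]).
#' @param rel_threshold Fraction in (0, 1); default 0.25.
#' @param mode `"max_fraction"` (default) or `"percentile"`.
#' @return An object of class `patch_set`: list with `labels` (raster of
#'   patch ids, NA outside patches), `table` (data frame: `id`,
#'   `n_cells`, `area_km2`, `centroid_x`, `centroid_y`), `cell_size`,
#'   `threshold` (the absolute cutoff used). An all-zero kernel yields
#'   an empty patch set.
#' @export
delineate_cores <- function(kernel, rel_threshold = 0.25,
                            mode = c("max_fraction", "percentile")) {
  mode <- match.arg(mode)
  k <- if (inherits(kernel, "kernel_surface")) kernel$k else kernel
  if (rel_threshold <= 0 || rel_threshold >= 1)
    stop("rel_threshold must be in (0, 1)")
  if (any(k$values < 0, na.rm = TRUE)) stop("kernel must be non-negative")
  g <- k$grid
  kmax <- suppressWarnings(max(k$values, na.rm = TRUE))
  cut <- if (mode == "max_fraction") rel_threshold * kmax
  else {
    pos <- k$values[!is.na(k$values) & k$values > 0]
    if (length(pos) == 0) Inf else unname(stats::quantile(pos, rel_threshold))
  }
  mask <- !is.na(k$values) & k$values > cut
  labels <- label_components(mask)
  ids <- sort(unique(labels[!is.na(labels)]))
  cell_area_km2 <- (g$cell_size / 1000)^2
  tab <- do.call(rbind, lapply(ids, function(i) {
    cells <- which(t(labels) == i)  # row-major
    ctr <- cell_centers(g, cells)
    data.frame(id = i, n_cells = length(cells),
               area_km2 = length(cells) * cell_area_km2,
               centroid_x = mean(ctr$x), centroid_y = mean(ctr$y))
  }))
  if (is.null(tab))
    tab <- data.frame(id = integer(0), n_cells = integer(0),
                      area_km2 = numeric(0), centroid_x = numeric(0),
                      centroid_y = numeric(0))
  structure(list(labels = raster_layer(labels, g), table = tab,
                 cell_size = g$cell_size,
                 threshold = if (is.finite(kmax)) cut else NA_real_),
            class = "patch_set")
}

## row-major cell ids of one patch
patch_cells <- function(patches, id) which(t(patches$labels$values) == id)

#' Class-level fragmentation metrics
#'
#' Computes the standard class-level metrics on a set of core patches:
#' number of patches (NP), percentage of landscape (PLAND), largest
#' patch index (LPI), and the area-weighted mean radius of gyration
#' (GYRATE_AM, "correlation length"). The radius of gyration of a patch
#' is the mean distance of its cell centers to the patch centroid (0 for
#' a single-cell patch); GYRATE_AM weights patch values by patch area.
#'
#' @param patches A `patch_set`.
#' @param landscape_area_km2 Total landscape area (> 0), the denominator
#'   of PLAND and LPI.
#' @return List of class `class_metrics`: `np`, `pland` (%), `lpi` (%),
#'   `gyrate_am` (metres), plus `gyrate` (per-patch radii, metres).
#' @export
class_metrics <- function(patches, landscape_area_km2) {
  if (!is.finite(landscape_area_km2) || landscape_area_km2 <= 0)
    stop("landscape_area_km2 must be > 0")
  tab <- patches$table
  if (nrow(tab) == 0L)
    return(structure(list(np = 0L, pland = 0, lpi = 0, gyrate_am = 0,
                          gyrate = numeric(0)),
                     class = "class_metrics"))
  g <- patches$labels$grid
  gy <- vapply(seq_len(nrow(tab)), function(i) {
    ctr <- cell_centers(g, patch_cells(patches, tab$id[i]))
    mean(sqrt((ctr$x - mean(ctr$x))^2 + (ctr$y - mean(ctr$y))^2))
  }, 0)
  structure(list(np = nrow(tab),
                 pland = 100 * sum(tab$area_km2) / landscape_area_km2,
                 lpi = 100 * max(tab$area_km2) / landscape_area_km2,
                 gyrate_am = sum(tab$area_km2 * gy) / sum(tab$area_km2),
                 gyrate = stats::setNames(gy, tab$id)),
            class = "class_metrics")
}

## ---- vector overlays -------------------------------------------------

## Ray-casting point-in-polygon (even-odd rule), vectorized over points.
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  if (all(poly[1, ] == poly[n, ])) n <- n - 1L  # drop closing vertex
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly$x[i]; yi <- poly$y[i]; xj <- poly$x[j]; yj <- poly$y[j]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

in_any_polygon <- function(px, py, polygons) {
  inside <- rep(FALSE, length(px))
  for (poly in polygons) inside <- inside | point_in_polygon(px, py, poly)
  inside
}

## Liang-Barsky clipping: length of segment (x1,y1)-(x2,y2) inside the
## axis-aligned rectangle [xmin,xmax] x [ymin,ymax].
segment_length_in_rect <- function(x1, y1, x2, y2, xmin, xmax, ymin, ymax) {
  dx <- x2 - x1; dy <- y2 - y1
  t0 <- 0; t1 <- 1
  for (pq in list(c(-dx, x1 - xmin), c(dx, xmax - x1),
                  c(-dy, y1 - ymin), c(dy, ymax - y1))) {
    p <- pq[1]; q <- pq[2]
    if (p == 0) { if (q < 0) return(0) }
    else {
      r <- q / p
      if (p < 0) { if (r > t1) return(0); if (r > t0) t0 <- r }
      else { if (r < t0) return(0); if (r < t1) t1 <- r }
    }
  }
  (t1 - t0) * sqrt(dx^2 + dy^2)
}

## Total polyline length (metres) inside a set of cells (row-major ids).
road_length_in_cells <- function(grid, cells, roads) {
  if (length(cells) == 0L || length(roads) == 0L) return(0)
  rc <- cell_rowcol(grid, cells)
  cs <- grid$cell_size
  xmin <- grid$xmin + (rc[, "col"] - 1) * cs
  ymin <- grid$ymin + (grid$n_rows - rc[, "row"]) * cs
  total <- 0
  for (line in roads) {
    for (s in seq_len(nrow(line) - 1L)) {
      x1 <- line$x[s]; y1 <- line$y[s]; x2 <- line$x[s + 1]; y2 <- line$y[s + 1]
      sx <- range(x1, x2); sy <- range(y1, y2)
      cand <- which(xmin < sx[2] & xmin + cs > sx[1] &
                      ymin < sy[2] & ymin + cs > sy[1])
      # segments along a cell boundary: count once, attributing the edge
      # to the cell whose interior the boundary touches from below/left
      for (ci in cand)
        total <- total + segment_length_in_rect(
          x1, y1, x2, y2, xmin[ci], xmin[ci] + cs, ymin[ci], ymin[ci] + cs)
    }
  }
  total
}

#' Overlay statistics against protected areas and roads
#'
#' For a set of core patches (or a corridor mask), quantifies: extent
#' (km^2), extent and percentage inside protected-area polygons, total
#' road length inside (m) and road density (m/km^2). Protected coverage
#' uses the cell-center rule (a cell counts as protected iff its center
#' falls inside some polygon); road lengths are exact clipped segment
#' lengths against the cell squares.
#'
#' @param x A `patch_set`, or a logical/0-1 [raster_layer()] mask
#'   (e.g. a thresholded `corridor_surface`).
#' @param protected A `polygon_set` (list of closed rings), possibly
#'   empty.
#' @param roads A `polyline_set` (list of coordinate data frames),
#'   possibly empty.
#' @return Data frame of class `overlay_stats` with one row per patch
#'   plus a `total` row: columns `id`, `extent_km2`, `protected_km2`,
#'   `protected_pct`, `road_length_m`, `road_density_m_per_km2`.
#' @export
overlay_stats <- function(x, protected = list(), roads = list()) {
  if (inherits(x, "corridor_surface")) x <- x$c
  if (inherits(x, "raster_layer")) {
    mask <- !is.na(x$values) & x$values > 0
    labels <- label_components(mask)
    g <- x$grid
    patches <- structure(list(labels = raster_layer(labels, g)),
                         class = "patch_set")
    ids <- sort(unique(labels[!is.na(labels)]))
  } else {
    patches <- x
    g <- patches$labels$grid
    ids <- patches$table$id
  }
  cell_area_km2 <- (g$cell_size / 1000)^2
  rows <- lapply(ids, function(i) {
    cells <- patch_cells(patches, i)
    ctr <- cell_centers(g, cells)
    prot <- if (length(protected))
      sum(in_any_polygon(ctr$x, ctr$y, protected)) else 0
    extent <- length(cells) * cell_area_km2
    rl <- road_length_in_cells(g, cells, roads)
    data.frame(id = as.character(i), extent_km2 = extent,
               protected_km2 = prot * cell_area_km2,
               protected_pct = 100 * prot / length(cells),
               road_length_m = rl,
               road_density_m_per_km2 = rl / extent)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(id = character(0), extent_km2 = numeric(0),
                      protected_km2 = numeric(0), protected_pct = numeric(0),
                      road_length_m = numeric(0),
                      road_density_m_per_km2 = numeric(0))
  if (nrow(out) > 0) {
    tot_ext <- sum(out$extent_km2); tot_prot <- sum(out$protected_km2)
    tot_rl <- sum(out$road_length_m)
    out <- rbind(out, data.frame(
      id = "total", extent_km2 = tot_ext, protected_km2 = tot_prot,
      protected_pct = if (tot_ext > 0) 100 * tot_prot / tot_ext else 0,
      road_length_m = tot_rl,
      road_density_m_per_km2 = if (tot_ext > 0) tot_rl / tot_ext else 0))
  }
  rownames(out) <- NULL
  class(out) <- c("overlay_stats", "data.frame")
  out
}
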