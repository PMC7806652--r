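## Movement graph over a resistance raster: vertices are cells (row-major
## ids), edges connect 8-neighbour pairs of valid cells, and the step cost
## between adjacent cells a, b is ((r_a + r_b)/2) * cell_size, times
## sqrt(2) for diagonal moves. Cost units are therefore resistance-
## weighted metres: 50,000 cost units through resistance-1 habitat is
## 50 km of actual movement.
resistance_graph <- function(resistance) {
  g <- resistance$grid
  nr <- g$n_rows; nc <- g$n_cols; cs <- g$cell_size
  vals <- resistance$values
  valid <- !is.na(vals)
  idm <- matrix(seq_len(nr * nc), nr, nc, byrow = TRUE)
  edges <- list(); weights <- list(); e <- 0L
  offs <- list(c(0L, 1L, 1), c(1L, 0L, 1), c(1L, 1L, sqrt(2)),
               c(1L, -1L, sqrt(2)))
  for (o in offs) {
    dr <- o[1]; dc <- o[2]; mult <- o[3]
    r1 <- seq_len(nr - dr); c1 <- if (dc >= 0) seq_len(nc - dc) else (1 - dc):nc
    r2 <- r1 + dr; c2 <- c1 + dc
    ok <- valid[r1, c1, drop = FALSE] & valid[r2, c2, drop = FALSE]
    if (!any(ok)) next
    a <- idm[r1, c1, drop = FALSE][ok]
    b <- idm[r2, c2, drop = FALSE][ok]
    w <- (vals[r1, c1, drop = FALSE][ok] + vals[r2, c2, drop = FALSE][ok]) /
      2 * cs * mult
    e <- e + 1L
    edges[[e]] <- rbind(a, b); weights[[e]] <- w
  }
  el <- if (e > 0L) as.vector(do.call(cbind, edges)) else integer(0)
  graph <- igraph::add_edges(igraph::make_empty_graph(nr * nc,
                                                      directed = FALSE), el)
  list(graph = graph, weights = unlist(weights), grid = g, valid = valid)
}

## Resolve a source specification to row-major cell ids on valid cells.
source_cells <- function(resistance, sources) {
  g <- resistance$grid
  ids <- if (is.data.frame(sources) || inherits(sources, "occurrence_set")) {
    cells_from_xy(g, sources$x, sources$y)
  } else if (is.matrix(sources) && ncol(sources) == 2) {
    cell_id(g, sources[, 1], sources[, 2])
  } else {
    as.integer(sources)
  }
  vm <- values_rowmajor(resistance)
  if (any(is.na(vm[ids])))
    stop("placement error: source cell(s) fall on nodata")
  ids
}

## Cost distance from each source separately: |sources| x ncells matrix.
## Coincident sources are valid (each contributes its own row).
cost_distance_matrix <- function(rg, source_ids) {
  uids <- unique(source_ids)
  d <- igraph::distances(rg$graph, v = uids, weights = rg$weights,
                         algorithm = "dijkstra")
  d[match(source_ids, uids), , drop = FALSE]
}

## Minimum cost distance over a source set in a single Dijkstra run,
## via a zero-weight virtual vertex attached to every source cell.
multi_source_cost <- function(rg, source_ids) {
  n <- igraph::vcount(rg$graph)
  gg <- igraph::add_vertices(rg$graph, 1)
  gg <- igraph::add_edges(gg, as.vector(rbind(n + 1L, source_ids)))
  w <- c(rg$weights, rep(0, length(source_ids)))
  d <- igraph::distances(gg, v = n + 1L, weights = w,
                         algorithm = "dijkstra")[1, ]
  d[seq_len(n)]
}

#' Accumulated cost distance from a source set
#'
#' Minimal accumulated movement cost from the nearest source cell to
#' every cell of the landscape, over 8-connected paths with step cost
#' `mean(resistance of the two cells) * cell_size` (`* sqrt(2)` for
#' diagonal steps); Dijkstra's algorithm on the raster movement graph.
#' Cost units are resistance-weighted metres.
#'
#' @param resistance A `resistance_surface` (or any [raster_layer()] of
#'   positive per-cell resistance).
#' @param sources Source cells: an `occurrence_set`/data frame with
#'   `x`, `y`; a 2-column (row, col) matrix; or integer cell ids.
#' @param max_cost Optional cost ceiling; cells farther than this are
#'   reported unreached (`Inf`).
#' @return A [raster_layer()] of accumulated cost (`0` at sources, `Inf`
#'   where unreachable, `NA` at nodata), with attribute `sources`.
#' @export
cost_distance <- function(resistance, sources, max_cost = NULL) {
  ids <- source_cells(resistance, sources)
  if (length(ids) == 0L) stop("sources must be non-empty")
  rg <- resistance_graph(resistance)
  cd <- multi_source_cost(rg, ids)
  if (!is.null(max_cost)) cd[cd > max_cost] <- Inf
  cd[!as.vector(t(rg$valid))] <- NA_real_
  out <- raster_from_rowmajor(cd, resistance$grid)
  attr(out, "sources") <- ids
  out
}

#' Cumulative resistant kernel
#'
#' Around each source, the dispersal kernel discounts with accumulated
#' movement cost and is truncated at the dispersal cost threshold `D`:
#' the default linear kernel is `k_s(x) = max(0, 1 - cd_s(x)/D)` (peak 1
#' at the source, 0 at cost `D`), and the cumulative surface sums the
#' per-source kernels, estimating the expected rate of movement through
#' each cell given all sources. A cell is within the kernel's reach iff
#' its accumulated cost is at most `D`; on uniform resistance `r`, the
#' cardinal-axis reach is `D / r` metres.
#'
#' @inheritParams cost_distance
#' @param D Dispersal cost threshold (> 0), in cost units
#'   (resistance-weighted metres).
#' @param shape `"linear"` (default) or `"gaussian"`
#'   (`exp(-(3 cd / D)^2 / 2)`, truncated at `D`).
#' @return An object of class `kernel_surface`: list with `k` (the
#'   cumulative kernel [raster_layer()]), `reached` (logical raster of
#'   cells with cost distance <= `D` from some source), `D`, `n_sources`,
#'   `shape`.
#' @export
resistant_kernel <- function(resistance, sources, D,
                             shape = c("linear", "gaussian")) {
  shape <- match.arg(shape)
  if (!is.finite(D) || D <= 0) stop("dispersal threshold D must be > 0")
  ids <- source_cells(resistance, sources)
  rg <- resistance_graph(resistance)
  cd <- cost_distance_matrix(rg, ids)
  per <- if (shape == "linear") {
    x <- 1 - cd / D; x[x < 0] <- 0; x
  } else exp(-(3 * cd / D)^2 / 2) * (cd <= D)
  k <- if (length(ids) == 1L) as.vector(per) else colSums(per)
  reached <- if (length(ids) == 1L) as.vector(cd) <= D
  else apply(cd <= D, 2, any)
  nodata <- !as.vector(t(rg$valid))
  k[nodata] <- NA_real_
  reached[nodata] <- NA
  structure(list(k = raster_from_rowmajor(k, resistance$grid),
                 reached = raster_from_rowmajor(reached * 1, resistance$grid),
                 D = D, n_sources = length(ids), shape = shape),
            class = "kernel_surface")
}

#' Least-cost path between two cells
#'
#' The 8-connected path achieving the minimal accumulated cost between
#' two cells (ties resolved deterministically by the shortest-path
#' search's fixed visiting order).
#'
#' @inheritParams cost_distance
#' @param a,b Single cells (same specifications as `sources`).
#' @return An object of class `lcp_path`: list with `cells` (n x 2
#'   row/col matrix), `ids`, `cost`, `from`, `to`.
#' @export
least_cost_path <- function(resistance, a, b) {
  ia <- source_cells(resistance, a)[1]
  ib <- source_cells(resistance, b)[1]
  rg <- resistance_graph(resistance)
  if (ia == ib)
    return(structure(list(cells = cell_rowcol(rg$grid, ia), ids = ia,
                          cost = 0, from = ia, to = ib),
                     class = "lcp_path"))
  sp <- suppressWarnings(
    igraph::shortest_paths(rg$graph, from = ia, to = ib,
                           weights = rg$weights, output = "vpath"))
  v <- as.integer(sp$vpath[[1]])
  if (length(v) == 0L)
    stop(sprintf("no-path error: cell %d is unreachable from cell %d", ib, ia))
  cost <- igraph::distances(rg$graph, v = ia, to = ib,
                            weights = rg$weights)[1, 1]
  structure(list(cells = cell_rowcol(rg$grid, v), ids = v, cost = cost,
                 from = ia, to = ib),
            class = "lcp_path")
}

## Dilate a set of cell ids by a circular buffer (radius in metres).
dilate_cells <- function(grid, ids, radius) {
  if (radius <= 0) return(unique(ids))
  h <- floor(radius / grid$cell_size)
  offs <- which(circle_kernel(radius / grid$cell_size) == 1, arr.ind = TRUE)
  offs <- offs - (h + 1L)
  rc <- cell_rowcol(grid, ids)
  rr <- rep(rc[, 1], each = nrow(offs)) + offs[, 1]
  cc <- rep(rc[, 2], each = nrow(offs)) + offs[, 2]
  ok <- rr >= 1L & rr <= grid$n_rows & cc >= 1L & cc <= grid$n_cols
  unique(cell_id(grid, rr[ok], cc[ok]))
}

#' Factorial least-cost-path corridor surface
#'
#' Computes the least-cost path between every unordered pair of source
#' points, dilates each path by `buffer_radius`, and sums the per-pair
#' incidences into a corridor-strength raster. Unreachable pairs are
#' skipped with a warning and recorded.
#'
#' @inheritParams cost_distance
#' @param buffer_radius Path buffer in metres (default one cell).
#' @return An object of class `corridor_surface`: list with `c` (the
#'   summed-incidence [raster_layer()]), `n_pairs` (pairs attempted),
#'   `skipped` (matrix of unreachable pairs), `buffer_radius`.
#' @export
factorial_lcp <- function(resistance, sources, buffer_radius = NULL) {
  ids <- unique(source_cells(resistance, sources))
  if (length(ids) < 2) stop("need at least 2 distinct sources")
  g <- resistance$grid
  if (is.null(buffer_radius)) buffer_radius <- g$cell_size
  rg <- resistance_graph(resistance)
  acc <- numeric(g$n_rows * g$n_cols)
  skipped <- NULL
  n_pairs <- 0L
  for (i in seq_len(length(ids) - 1L)) {
    to <- ids[(i + 1L):length(ids)]
    sp <- suppressWarnings(
      igraph::shortest_paths(rg$graph, from = ids[i], to = to,
                             weights = rg$weights, output = "vpath"))
    for (j in seq_along(to)) {
      n_pairs <- n_pairs + 1L
      v <- as.integer(sp$vpath[[j]])
      if (length(v) == 0L) {
        skipped <- rbind(skipped, c(ids[i], to[j]))
        next
      }
      cells <- dilate_cells(g, v, buffer_radius)
      acc[cells] <- acc[cells] + 1
    }
  }
  if (!is.null(skipped))
    warning(sprintf("%d unreachable source pair(s) skipped", nrow(skipped)))
  acc[!as.vector(t(rg$valid))] <- NA_real_
  structure(list(c = raster_from_rowmajor(acc, g), n_pairs = n_pairs,
                 skipped = skipped, buffer_radius = buffer_radius),
            class = "corridor_surface")
}
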