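#' Raster grid specification
#'
#' Defines the georeferenced frame shared by every raster in an analysis:
#' number of rows and columns, square cell size in metres, and the map
#' coordinates of the lower-left corner. All geometry in this package is
#' planar, in projected map units (metres).
#'
#' @param n_rows,n_cols Grid dimensions (>= 1).
#' @param cell_size Cell edge length in metres (> 0).
#' @param xmin,ymin Map coordinates of the lower-left corner of the grid.
#' @param nodata_value Sentinel written to file for missing cells.
#' @param crs Free-text tag for the projected coordinate reference system.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, cell_size, xmin = 0, ymin = 0,
                      nodata_value = -9999, crs = "local-metres") {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) stop("grid dimensions must be >= 1")
  if (!is.finite(cell_size) || cell_size <= 0) stop("cell_size must be > 0")
  structure(list(n_rows = n_rows, n_cols = n_cols, cell_size = cell_size,
                 xmin = xmin, ymin = ymin, nodata_value = nodata_value,
                 crs = crs),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, %g m resolution, origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$xmin, x$ymin))
  invisible(x)
}

#' Raster layer
#'
#' A raster is a numeric matrix bound to a [grid_spec()]. Row 1 is the
#' northernmost row (the usual on-disk raster order); `NA` marks nodata.
#'
#' @param values Numeric matrix with `grid$n_rows` rows and `grid$n_cols`
#'   columns, or a single number recycled to the full grid.
#' @param grid A [grid_spec()].
#' @return An object of class `raster_layer`.
#' @export
raster_layer <- function(values, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (length(values) == 1L)
    values <- matrix(values, grid$n_rows, grid$n_cols)
  values <- as.matrix(values)
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols)
    stop("values matrix does not match grid dimensions")
  storage.mode(values) <- "double"
  structure(list(values = values, grid = grid), class = "raster_layer")
}

#' @export
print.raster_layer <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<raster_layer> %d x %d (%g m cells); range [%g, %g], %d nodata\n",
              x$grid$n_rows, x$grid$n_cols, x$grid$cell_size,
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA,
              sum(is.na(x$values))))
  invisible(x)
}

#' Test whether two rasters share the same grid frame
#'
#' @param a,b `raster_layer` or `grid_spec` objects.
#' @return `TRUE` if dimensions, cell size and origin agree.
#' @export
same_grid <- function(a, b) {
  ga <- if (inherits(a, "raster_layer")) a$grid else a
  gb <- if (inherits(b, "raster_layer")) b$grid else b
  isTRUE(ga$n_rows == gb$n_rows && ga$n_cols == gb$n_cols &&
           all.equal(ga$cell_size, gb$cell_size) == TRUE &&
           all.equal(c(ga$xmin, ga$ymin), c(gb$xmin, gb$ymin)) == TRUE)
}

stop_if_misaligned <- function(a, b, what = "raster") {
  if (!same_grid(a, b)) {
    ga <- if (inherits(a, "raster_layer")) a$grid else a
    gb <- if (inherits(b, "raster_layer")) b$grid else b
    stop(sprintf(
      "alignment error: %s grid (%dx%d @ %gm, origin %g,%g) does not match reference grid (%dx%d @ %gm, origin %g,%g)",
      what, ga$n_rows, ga$n_cols, ga$cell_size, ga$xmin, ga$ymin,
      gb$n_rows, gb$n_cols, gb$cell_size, gb$xmin, gb$ymin))
  }
  invisible(TRUE)
}

## Cell indexing: cells are numbered 1..n_rows*n_cols in row-major order
## (row 1 = north). Helpers convert between ids, (row, col) and map x/y.

cell_id <- function(grid, row, col) (row - 1L) * grid$n_cols + col

cell_rowcol <- function(grid, id) {
  id <- as.integer(id)
  row <- (id - 1L) %/% grid$n_cols + 1L
  col <- (id - 1L) %% grid$n_cols + 1L
  cbind(row = row, col = col)
}

#' Map coordinates of cell centers
#'
#' @param grid A [grid_spec()].
#' @param id Cell ids (row-major, row 1 = north). Default: all cells.
#' @return Data frame with columns `id`, `x`, `y`.
#' @export
cell_centers <- function(grid, id = seq_len(grid$n_rows * grid$n_cols)) {
  rc <- cell_rowcol(grid, id)
  data.frame(id = as.integer(id),
             x = grid$xmin + (rc[, "col"] - 0.5) * grid$cell_size,
             y = grid$ymin + (grid$n_rows - rc[, "row"] + 0.5) * grid$cell_size)
}

#' Cell ids containing given map coordinates
#'
#' @param grid A [grid_spec()].
#' @param x,y Coordinate vectors in map units.
#' @return Integer cell ids; coordinates outside the grid extent are an error.
#' @export
cells_from_xy <- function(grid, x, y) {
  col <- floor((x - grid$xmin) / grid$cell_size) + 1L
  row <- grid$n_rows - floor((y - grid$ymin) / grid$cell_size)
  # points exactly on the top/right edge belong to the last cell
  col[x == grid$xmin + grid$n_cols * grid$cell_size] <- grid$n_cols
  row[y == grid$ymin + grid$n_rows * grid$cell_size] <- 1L
  bad <- col < 1L | col > grid$n_cols | row < 1L | row > grid$n_rows
  if (any(bad))
    stop(sprintf("%d point(s) fall outside the grid extent", sum(bad)))
  cell_id(grid, as.integer(row), as.integer(col))
}

#' Extract raster values at map coordinates
#'
#' @param raster A [raster_layer()].
#' @param x,y Coordinates in map units.
#' @return Numeric vector of cell values (NA at nodata cells).
#' @export
extract_values <- function(raster, x, y) {
  ids <- cells_from_xy(raster$grid, x, y)
  t(raster$values)[ids]  # row-major lookup
}

## row-major vector view of a raster matrix
values_rowmajor <- function(raster) as.vector(t(raster$values))

raster_from_rowmajor <- function(v, grid)
  raster_layer(matrix(v, grid$n_rows, grid$n_cols, byrow = TRUE), grid)

#' Read and write rasters as ESRI ASCII grids
#'
#' Plain-text raster exchange format (`ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value` header followed by rows north to south).
#' Round-trips values, cell size, origin and the nodata mask.
#'
#' @param path File path.
#' @param raster A [raster_layer()].
#' @param digits Significant digits written (default 15, enough for a
#'   double to round-trip through text in practice).
#' @return `read_asc()` returns a [raster_layer()]; `write_asc()` returns
#'   `path` invisibly.
#' @export
read_asc <- function(path) {
  lines <- readLines(path, n = 6L)
  kv <- strsplit(trimws(lines), "\\s+")
  hdr <- stats::setNames(vapply(kv, function(p) as.numeric(p[2]), 0),
                         tolower(vapply(kv, `[`, "", 1)))
  grid <- grid_spec(hdr[["nrows"]], hdr[["ncols"]], hdr[["cellsize"]],
                    xmin = hdr[["xllcorner"]], ymin = hdr[["yllcorner"]],
                    nodata_value = if ("nodata_value" %in% names(hdr))
                      hdr[["nodata_value"]] else -9999)
  vals <- scan(path, skip = 6L, quiet = TRUE)
  m <- matrix(vals, grid$n_rows, grid$n_cols, byrow = TRUE)
  m[m == grid$nodata_value] <- NA_real_
  raster_layer(m, grid)
}

#' @rdname read_asc
#' @export
write_asc <- function(raster, path, digits = 15) {
  g <- raster$grid
  hdr <- c(sprintf("ncols %d", g$n_cols),
           sprintf("nrows %d", g$n_rows),
           sprintf("xllcorner %.10g", g$xmin),
           sprintf("yllcorner %.10g", g$ymin),
           sprintf("cellsize %.10g", g$cell_size),
           sprintf("NODATA_value %.10g", g$nodata_value))
  m <- raster$values
  m[is.na(m)] <- g$nodata_value
  rows <- apply(m, 1L, function(r) paste(formatC(r, digits = digits,
                                                 format = "g"),
                                         collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

## Run code with a temporarily fixed RNG state; restores the caller's state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}
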