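#' Generate a spatially autocorrelated covariate field
#'
#' Produces a zero-mean, unit-variance Gaussian random field by smoothing
#' white noise with an isotropic Gaussian filter and re-standardizing.
#' The field stands in for continuous environmental covariates
#' (topographic roughness, NDVI, human footprint, climate layers) whose
#' real-world counterparts the pipeline would ingest as rasters.
#'
#' `autocorr_range` is the distance at which spatial correlation has
#' decayed to roughly 0.1: the filter standard deviation is
#' `autocorr_range / (3 * cell_size)` cells, and the Gaussian
#' autocorrelation function `exp(-d^2 / (4 sigma^2))` then drops to ~0.1
#' at `d = autocorr_range`. A range equal to one cell is therefore
#' effectively white noise at the cell scale.
#'
#' The noise is generated on a grid padded by four filter standard
#' deviations and cropped after smoothing, so there are no edge artefacts.
#'
#' @param grid A [grid_spec()].
#' @param autocorr_range Correlation range in metres (>= cell size).
#' @param seed Integer seed; the same (grid, range, seed) always
#'   reproduces the identical field.
#' @return A [raster_layer()] with mean 0 and standard deviation 1.
#' @export
generate_covariate_field <- function(grid, autocorr_range, seed) {
  if (!is.finite(autocorr_range) || autocorr_range < grid$cell_size)
    stop("autocorr_range must be >= cell_size and positive")
  sigma <- autocorr_range / (3 * grid$cell_size)
  pad <- ceiling(4 * sigma) + 1L
  nr <- grid$n_rows + 2L * pad
  nc <- grid$n_cols + 2L * pad
  noise <- with_seed(seed, matrix(stats::rnorm(nr * nc), nr, nc))
  h <- max(1L, ceiling(4 * sigma))
  g1 <- exp(-(-h:h)^2 / (2 * sigma^2))
  k <- outer(g1, g1)
  k <- k / sum(k)
  sm <- conv2_same(noise, k)
  field <- sm[pad + seq_len(grid$n_rows), pad + seq_len(grid$n_cols)]
  field <- (field - mean(field)) / stats::sd(field)
  raster_layer(field, grid)
}

#' Classify a continuous field into land-cover classes
#'
#' Thresholds a continuous covariate field at the given quantile breaks,
#' producing an integer class raster (1..k). Used together with
#' [class_density()] to emulate categorical land-cover inputs.
#'
#' @param field A [raster_layer()].
#' @param breaks Quantile breakpoints in (0,1), strictly increasing.
#' @return Integer-valued [raster_layer()] with classes `1..length(breaks)+1`.
#' @export
land_cover_classes <- function(field, breaks = c(1/3, 2/3)) {
  q <- stats::quantile(field$values, probs = breaks, na.rm = TRUE)
  cls <- findInterval(field$values, q) + 1
  cls[is.na(field$values)] <- NA_real_
  raster_layer(matrix(cls, nrow(field$values), ncol(field$values)), field$grid)
}

#' Per-class density of a categorical raster
#'
#' Fraction of cells of a given class within a circular moving window
#' (focal mean of the class indicator), mirroring the standard way
#' categorical land cover enters a suitability model as a density map.
#'
#' @param classes Integer class raster from [land_cover_classes()].
#' @param class Class value whose density is wanted.
#' @param radius Window radius in metres (default 2500, a 2.5 km window).
#' @return A [raster_layer()] with values in \[0,1\].
#' @export
class_density <- function(classes, class, radius = 2500) {
  ind <- raster_layer((classes$values == class) * 1, classes$grid)
  ind$values[is.na(classes$values)] <- NA_real_
  out <- focal_mean(ind, radius)
  out$values <- pmin(pmax(out$values, 0), 1)  # guard FFT round-off
  out
}

#' Generate a known true suitability surface
#'
#' Builds the synthetic "truth" the estimation pipeline is asked to
#' recover: habitat suitability is the logistic transform of a linear
#' combination of the covariates after focal averaging at a single known
#' spatial scale (`true_scale`). Scale-selection tests ask whether the
#' pipeline identifies `true_scale` among its candidates.
#'
#' @param covariates List of [raster_layer()]s on a shared grid.
#' @param coefficients Numeric weights, one per covariate.
#' @param true_scale Focal radius (metres) at which the covariates drive
#'   suitability.
#' @param intercept Linear-predictor intercept (default 0, so suitability
#'   is centred near 0.5 for standardized covariates).
#' @param seed Optional integer recorded for provenance.
#' @return An object of class `synthetic_truth`: list with `suitability`
#'   (a [raster_layer()] in (0,1)), `true_scale`, `coefficients`, `seed`.
#' @export
generate_true_suitability <- function(covariates, coefficients, true_scale,
                                      intercept = 0, seed = NULL) {
  if (length(covariates) != length(coefficients))
    stop("need exactly one coefficient per covariate")
  g <- covariates[[1]]$grid
  for (cv in covariates) stop_if_misaligned(cv, g, "covariate")
  lp <- matrix(intercept, g$n_rows, g$n_cols)
  for (i in seq_along(covariates)) {
    sm <- focal_mean(covariates[[i]], true_scale)
    lp <- lp + coefficients[i] * sm$values
  }
  hs <- stats::plogis(lp)
  structure(list(suitability = raster_layer(hs, g),
                 true_scale = true_scale,
                 coefficients = coefficients, seed = seed),
            class = "synthetic_truth")
}

#' Sample presence points proportionally to suitability
#'
#' Draws `n` presence records with per-cell probability proportional to
#' the suitability surface (cells may be drawn more than once; points are
#' placed at cell centers). Emulates opportunistic occurrence records
#' concentrated in good habitat.
#'
#' @param truth A `synthetic_truth` or a suitability [raster_layer()].
#' @param n Number of presence points (>= 1).
#' @param seed Integer seed.
#' @param effort Optional [raster_layer()] of relative observation effort
#'   multiplying the sampling intensity (e.g. road-proximity bias);
#'   default none (uniform effort).
#' @return An `occurrence_set` data frame (columns id, x, y, label).
#' @export
sample_occurrences <- function(truth, n, seed, effort = NULL) {
  hs <- if (inherits(truth, "synthetic_truth")) truth$suitability else truth
  if (n < 1) stop("n must be >= 1")
  g <- hs$grid
  w <- values_rowmajor(hs)
  if (!is.null(effort)) {
    stop_if_misaligned(effort, g, "effort")
    w <- w * values_rowmajor(effort)
  }
  valid <- which(!is.na(w))
  if (n > length(valid))
    stop(sprintf("n = %d exceeds the %d non-nodata cells", n, length(valid)))
  if (sum(w[valid]) <= 0) stop("suitability is zero everywhere")
  ids <- with_seed(seed,
                   sample(valid, n, replace = TRUE, prob = w[valid]))
  ctr <- cell_centers(g, ids)
  occurrence_set(data.frame(id = seq_len(n), x = ctr$x, y = ctr$y,
                            label = "presence"), crs = g$crs)
}

#' Generate synthetic protected-area and road overlays
#'
#' Protected areas are seeded axis-aligned rectangles (snapped to cell
#' boundaries so raster overlays are exact); roads are a rectilinear
#' lattice of straight polylines at the given spacing with seeded jitter
#' of each line's offset, clipped to the grid extent. The lattice makes
#' total road length predictable, which the overlay statistics tests use.
#'
#' @param grid A [grid_spec()].
#' @param n_protected Number of protected polygons (>= 0).
#' @param road_spacing Lattice spacing in metres; `Inf` for no roads.
#' @param seed Integer seed.
#' @param size_range Rectangle edge lengths as fractions of the extent
#'   (default 0.1 to 0.3).
#' @return List with `protected` (a `polygon_set`: list of closed-ring
#'   data frames with columns x, y) and `roads` (a `polyline_set`: list
#'   of data frames with columns x, y).
#' @export
generate_overlays <- function(grid, n_protected, road_spacing, seed,
                              size_range = c(0.1, 0.3)) {
  if (n_protected < 0) stop("n_protected must be >= 0")
  W <- grid$n_cols * grid$cell_size
  H <- grid$n_rows * grid$cell_size
  snap <- function(v) round(v / grid$cell_size) * grid$cell_size
  res <- with_seed(seed, {
    polys <- vector("list", n_protected)
    for (i in seq_len(n_protected)) {
      w <- snap(stats::runif(1, size_range[1], size_range[2]) * W)
      h <- snap(stats::runif(1, size_range[1], size_range[2]) * H)
      w <- max(w, grid$cell_size); h <- max(h, grid$cell_size)
      x0 <- grid$xmin + snap(stats::runif(1, 0, W - w))
      y0 <- grid$ymin + snap(stats::runif(1, 0, H - h))
      polys[[i]] <- data.frame(x = c(x0, x0 + w, x0 + w, x0, x0),
                               y = c(y0, y0, y0 + h, y0 + h, y0))
    }
    roads <- list()
    if (is.finite(road_spacing) && road_spacing > 0) {
      jit <- 0.2 * road_spacing
      xs <- seq(grid$xmin + road_spacing, grid$xmin + W - road_spacing / 2,
                by = road_spacing)
      for (x in xs) {
        xj <- min(max(x + stats::runif(1, -jit, jit), grid$xmin), grid$xmin + W)
        roads[[length(roads) + 1L]] <-
          data.frame(x = c(xj, xj), y = c(grid$ymin, grid$ymin + H))
      }
      ys <- seq(grid$ymin + road_spacing, grid$ymin + H - road_spacing / 2,
                by = road_spacing)
      for (y in ys) {
        yj <- min(max(y + stats::runif(1, -jit, jit), grid$ymin), grid$ymin + H)
        roads[[length(roads) + 1L]] <-
          data.frame(x = c(grid$xmin, grid$xmin + W), y = c(yj, yj))
      }
    }
    list(polys = polys, roads = roads)
  })
  list(protected = structure(res$polys, class = "polygon_set"),
       roads = structure(res$roads, class = "polyline_set"))
}
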