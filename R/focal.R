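## 2D convolution via FFT. `k` must have odd dimensions; returns the
## "same"-sized result aligned on the center of `k`. Zero padding outside
## the matrix, so border cells simply see fewer neighbours.
conv2_same <- function(x, k) {
  nr <- nrow(x) + nrow(k) - 1L
  nc <- ncol(x) + ncol(k) - 1L
  xp <- matrix(0, nr, nc); xp[seq_len(nrow(x)), seq_len(ncol(x))] <- x
  kp <- matrix(0, nr, nc); kp[seq_len(nrow(k)), seq_len(ncol(k))] <- k
  res <- Re(stats::fft(stats::fft(xp) * stats::fft(kp), inverse = TRUE)) /
    (nr * nc)
  r0 <- (nrow(k) - 1L) / 2L
  c0 <- (ncol(k) - 1L) / 2L
  res[r0 + seq_len(nrow(x)), c0 + seq_len(ncol(x)), drop = FALSE]
}

## 0/1 mask of cell offsets whose centers lie within `radius_cells` of the
## focal cell (Euclidean, in cell units). r = 2 gives the familiar
## 13-cell discrete circle.
circle_kernel <- function(radius_cells) {
  h <- floor(radius_cells)
  d <- outer((-h:h)^2, (-h:h)^2, "+")
  (d <= radius_cells^2) * 1
}

#' Circular focal mean
#'
#' Replaces each cell by the mean of the input over the circular
#' neighbourhood of the given radius (cell centers within `radius` of the
#' focal cell center). Nodata cells are excluded from the mean, and cells
#' near the border average over the in-bounds part of the window only.
#' This is the moving-window operation used to build multi-scale
#' covariates (e.g. land-cover density maps, covariates smoothed at
#' candidate habitat-selection scales).
#'
#' @param raster A [raster_layer()].
#' @param radius Neighbourhood radius in metres; must be at least half a
#'   cell (so the window is never empty).
#' @return A [raster_layer()] on the same grid; nodata cells stay nodata.
#' @export
focal_mean <- function(raster, radius) {
  g <- raster$grid
  if (!is.finite(radius) || radius < g$cell_size / 2)
    stop("radius must be >= half the cell size")
  k <- circle_kernel(radius / g$cell_size)
  vals <- raster$values
  valid <- !is.na(vals)
  v0 <- vals; v0[!valid] <- 0
  num <- conv2_same(v0, k)
  den <- conv2_same(valid * 1, k)
  out <- num / pmax(den, .Machine$double.eps)
  out[!valid] <- NA_real_
  raster_layer(out, g)
}
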