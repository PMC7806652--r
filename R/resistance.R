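#' Transform habitat suitability to movement resistance
#'
#' Applies the negative-exponential transform `raw = base^(-HS)` and then
#' rescales linearly onto `[rmin, rmax]` using the analytic extremes
#' `base^-1` (HS = 1) and `base^0 = 1` (HS = 0) as anchors, so that
#' perfect habitat always maps to `rmin` and non-habitat to `rmax`
#' regardless of the values present in a particular map. With the
#' defaults (base 1000, range 1-10) the transform is strictly decreasing
#' and strongly convex: resistance stays low across most of the
#' suitability range and rises steeply only as suitability approaches 0,
#' reflecting the view that animals move readily through all but the
#' worst habitat.
#'
#' @param hs A suitability [raster_layer()] or numeric vector with values
#'   in \[0, 1\].
#' @param base Exponential base (default 1000).
#' @param rmin,rmax Output range (defaults 1 and 10).
#' @return Same shape as the input; a `resistance_surface` raster when a
#'   raster is supplied. Nodata propagates.
#' @export
suitability_to_resistance <- function(hs, base = 1000, rmin = 1, rmax = 10) {
  is_raster <- inherits(hs, "raster_layer")
  v <- if (is_raster) hs$values else hs
  bad <- sum(v < 0 | v > 1, na.rm = TRUE)
  if (bad > 0)
    stop(sprintf("suitability outside [0,1] at %d cell(s)", bad))
  lo <- base^(-1)
  raw <- base^(-v)
  r <- rmin + (rmax - rmin) * (raw - lo) / (1 - lo)
  if (!is_raster) return(r)
  out <- raster_layer(r, hs$grid)
  class(out) <- c("resistance_surface", class(out))
  attr(out, "source") <- attr(hs, "provenance")
  out
}
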