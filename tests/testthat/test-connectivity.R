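uniform_res <- function(nr, nc, cs = 1000, val = 1)
  raster_layer(matrix(val, nr, nc), grid_spec(nr, nc, cs))

test_that("cost distance reproduces the step-cost metric", {
  # 1x3 strip of resistance 1 at 1 km cells: two unit steps = 2000
  cd <- cost_distance(uniform_res(1, 3), 1L)
  expect_equal(as.vector(cd$values), c(0, 1000, 2000))
  # diagonal neighbour costs sqrt(2) * 1000
  cd2 <- cost_distance(uniform_res(2, 2), 1L)
  expect_equal(cd2$values[2, 2], 1000 * sqrt(2))
  # mixed resistance: step cost is the mean of the two cells
  r <- raster_layer(matrix(c(1, 3, 5), 1, 3), grid_spec(1, 3, 1000))
  cd3 <- cost_distance(r, 1L)
  expect_equal(as.vector(cd3$values), c(0, 2000, 6000))
  # max_cost truncates reachability
  cd4 <- cost_distance(uniform_res(1, 5), 1L, max_cost = 2500)
  expect_equal(as.vector(cd4$values), c(0, 1000, 2000, Inf, Inf))
  # sources on nodata are rejected
  rn <- uniform_res(2, 2); rn$values[1, 1] <- NA
  expect_error(cost_distance(rn, 1L), "nodata")
})

test_that("raster Dijkstra agrees with exhaustive search on random small grids", {
  for (seed in 1:20) {
    set.seed(seed)
    nr <- sample(2:4, 1); nc <- sample(2:4, 1)
    m <- matrix(runif(nr * nc, 1, 10), nr, nc)
    if (seed %% 3 == 0) m[sample(nr * nc, 1)] <- NA
    start <- sample(which(!is.na(t(m))), 1)
    r <- raster_layer(m, grid_spec(nr, nc, 1000))
    got <- kernelscape:::values_rowmajor(cost_distance(r, start))
    want <- bf_cost_distance(m, 1000, start)
    valid <- !is.na(kernelscape:::values_rowmajor(r))
    expect_equal(got[valid], want[valid], tolerance = 1e-9)
  }
})

test_that("cost distance satisfies the triangle inequality", {
  set.seed(30)
  m <- matrix(runif(64, 1, 10), 8, 8)
  r <- raster_layer(m, grid_spec(8, 8, 1000))
  cells <- sample(64, 6)
  cd <- lapply(cells, function(s)
    kernelscape:::values_rowmajor(cost_distance(r, s)))
  for (i in 1:6) for (j in 1:6) for (k in 1:6)
    expect_lte(cd[[i]][cells[j]], cd[[i]][cells[k]] + cd[[k]][cells[j]] + 1e-9)
})

test_that("resistant kernels decay linearly with cost and add over sources", {
  r <- uniform_res(41, 41)
  src <- matrix(c(21L, 21L), 1, 2)
  k <- resistant_kernel(r, src, 20000)
  expect_equal(k$k$values[21, 21], 1)              # peak 1 at the source
  expect_equal(k$k$values[21, 31], 0.5)            # 10 km east: 1 - 10/20
  expect_equal(k$k$values[21, 41], 0)              # at the threshold
  expect_equal(k$n_sources, 1)
  # additivity: coincident sources double the kernel
  k2 <- resistant_kernel(r, rbind(src, src), 20000)
  expect_equal(k2$k$values, 2 * k$k$values)
  # kernel positive only where cost distance < D
  cd <- cost_distance(r, src)
  expect_identical(k$k$values > 0, cd$values < 20000)
  # reach (cd <= D) on uniform resistance: the analytic cone radius
  expect_identical(k$reached$values == 1, cd$values <= 20000)
  expect_error(resistant_kernel(r, src, -5), "D must be")
})

test_that("kernel support nests across increasing thresholds", {
  fx <- fixture_landscape()
  ks <- lapply(c(5000, 10000, 20000), function(D)
    resistant_kernel(fx$resistance, fx$presences, D))
  for (i in 1:2) {
    a <- ks[[i]]$k$values; b <- ks[[i + 1]]$k$values
    expect_true(all(b[a > 0] > 0))       # support nests
    expect_true(all(b >= a))             # and values grow pointwise
    expect_true(all(ks[[i + 1]]$reached$values[ks[[i]]$reached$values == 1] == 1))
  }
})

test_that("least-cost paths achieve the cost distance and route through gaps", {
  r <- uniform_res(9, 9)
  a <- matrix(c(5L, 1L), 1, 2); b <- matrix(c(5L, 9L), 1, 2)
  p <- least_cost_path(r, a, b)
  expect_equal(p$cost, 8000)
  expect_true(all(p$cells[, "row"] == 5))  # straight cardinal path
  # consecutive cells are 8-neighbours and the cost matches cost_distance
  steps <- abs(diff(p$cells))
  expect_true(all(steps <= 1) && all(rowSums(steps) >= 1))
  # wall with one gap: the path must pass the gap cell
  m <- matrix(1, 9, 9); m[, 5] <- 1000; m[3, 5] <- 1
  rw <- raster_layer(m, grid_spec(9, 9, 1000))
  pw <- least_cost_path(rw, a, b)
  expect_true(any(pw$cells[, "row"] == 3 & pw$cells[, "col"] == 5))
  expect_equal(pw$cost,
               kernelscape:::values_rowmajor(cost_distance(rw, a))[
                 kernelscape:::cell_id(rw$grid, 5L, 9L)],
               tolerance = 1e-9)
  # degenerate: a == b
  p0 <- least_cost_path(r, a, a)
  expect_equal(p0$cost, 0)
  expect_equal(nrow(p0$cells), 1)
  # unreachable target raises a no-path error
  rn <- uniform_res(3, 3); rn$values[, 2] <- NA
  expect_error(least_cost_path(rn, matrix(c(2L, 1L), 1, 2),
                               matrix(c(2L, 3L), 1, 2)), "no-path")
})

test_that("factorial least-cost paths sum pairwise incidences", {
  r <- uniform_res(9, 13)
  # 2 sources: single path of incidence 1
  two <- rbind(c(5L, 2L), c(5L, 12L))
  c2 <- factorial_lcp(r, two, buffer_radius = 0)
  expect_equal(max(c2$c$values, na.rm = TRUE), 1)
  expect_equal(c2$n_pairs, 1)
  # 3 collinear sources, zero buffer: cells strictly between the outer
  # sources (excluding the middle source itself) carry 2 coincident paths
  three <- rbind(c(5L, 2L), c(5L, 7L), c(5L, 12L))
  c3 <- factorial_lcp(r, three, buffer_radius = 0)
  between <- setdiff(3:11, 7)
  expect_true(all(c3$c$values[5, between] == 2))
  expect_equal(c3$c$values[5, 7], 3)  # middle source carries all 3 pairs
  # pair-count bound: n(n-1)/2
  expect_lte(max(c3$c$values, na.rm = TRUE), 3)
  # unreachable pairs are skipped with a warning, not an error
  rn <- uniform_res(3, 5); rn$values[, 3] <- NA
  expect_warning(cf <- factorial_lcp(rn, rbind(c(2L, 1L), c(2L, 5L)),
                                     buffer_radius = 0), "unreachable")
  expect_equal(nrow(cf$skipped), 1)
  # buffering dilates the corridor footprint
  cb <- factorial_lcp(r, two, buffer_radius = 1000)
  expect_gt(sum(cb$c$values > 0), sum(c2$c$values > 0))
})
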