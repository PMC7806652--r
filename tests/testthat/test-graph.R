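chain3 <- function(p12, p23, p13 = 0, areas = c(1, 1, 1), A_L = 10) {
  p <- diag(3)
  p[1, 2] <- p[2, 1] <- p12
  p[2, 3] <- p[3, 2] <- p23
  p[1, 3] <- p[3, 1] <- p13
  patch_graph(areas = areas, p = p, A_L = A_L)
}

test_that("dispersal probabilities are calibrated at the threshold distance", {
  d <- matrix(c(0, 50000, 50000, 0), 2, 2)
  g <- patch_graph(areas = c(1, 1), d = d, A_L = 10, D = 50000, p_at_D = 0.5)
  expect_equal(g$p[1, 2], 0.5)                     # p(D) = p_at_D exactly
  expect_true(g$links[1, 2])
  d2 <- matrix(c(0, 100000, 100000, 0), 2, 2)
  g2 <- patch_graph(areas = c(1, 1), d = d2, A_L = 10, D = 50000, p_at_D = 0.5)
  expect_equal(g2$p[1, 2], 0.25)                   # exp(-2 ln 2) at 2D
  expect_false(g2$links[1, 2])
  # adjacent patches at distance 0: probability 1
  g0 <- patch_graph(areas = c(1, 1), d = matrix(0, 2, 2), A_L = 10,
                    D = 50000, p_at_D = 0.05)
  expect_equal(g0$p[1, 2], 1)
})

test_that("IIC and PC reproduce their closed-form small cases", {
  one <- patch_graph(areas = 4, p = matrix(1, 1, 1),
                     links = matrix(FALSE, 1, 1), A_L = 100)
  expect_equal(compute_iic(one), 0.0016)
  expect_equal(compute_pc(one), 0.0016)
  # two unit patches, A_L = 10
  unlinked <- patch_graph(areas = c(1, 1), p = diag(2), A_L = 10)
  expect_equal(compute_iic(unlinked), 0.02)
  linked <- patch_graph(areas = c(1, 1),
                        p = matrix(c(1, 0.5, 0.5, 1), 2, 2), A_L = 10)
  expect_equal(compute_iic(linked), 0.03)  # (1 + 1 + 2/2) / 100
  expect_equal(compute_pc(linked), 0.03)   # (1 + 1 + 2 * 0.5) / 100
  # stepping stone: the two-step product beats the direct link
  g3 <- chain3(0.7, 0.7, p13 = 0.2)
  ps <- kernelscape:::pstar_matrix(g3)
  expect_equal(ps[1, 3], 0.49)
})

test_that("IIC and PC match exhaustive path enumeration on random graphs", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(2:6, 1)
    areas <- runif(n, 0.5, 5)
    A_L <- sum(areas) * runif(1, 1.5, 3)
    p <- random_p_matrix(n)
    g <- patch_graph(areas = areas, p = p, A_L = A_L)
    links <- p > 0; diag(links) <- FALSE
    expect_equal(compute_pc(g), bf_pc(areas, p, A_L), tolerance = 1e-9)
    expect_equal(compute_iic(g), bf_iic(areas, links, A_L), tolerance = 1e-9)
  }
})

test_that("node importance reproduces the two-patch hand computation", {
  linked <- patch_graph(areas = c(1, 1),
                        p = matrix(c(1, 0.5, 0.5, 1), 2, 2), A_L = 10)
  ni <- node_importance(linked, "PC")
  expect_equal(ni$dX, c(200 / 3, 200 / 3), tolerance = 1e-9)
  expect_equal(ni$intra, c(100 / 3, 100 / 3), tolerance = 1e-9)
  expect_equal(ni$flux, c(100 / 3, 100 / 3), tolerance = 1e-9)
  expect_equal(ni$connector, c(0, 0), tolerance = 1e-9)
})

test_that("importance fractions close and are non-negative where required", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(3:6, 1)
    g <- patch_graph(areas = runif(n, 0.5, 5), p = random_p_matrix(n),
                     A_L = 50)
    for (index in c("PC", "IIC")) {
      ni <- node_importance(g, index)
      expect_equal(ni$dX, ni$intra + ni$flux + ni$connector,
                   tolerance = 1e-6)
      expect_true(all(ni$intra >= 0))
      expect_true(all(ni$flux >= 0))
    }
  }
})

test_that("an isolated patch's removal changes the index by exactly its intra term", {
  p <- diag(4)
  p[1, 2] <- p[2, 1] <- 0.6
  p[2, 3] <- p[3, 2] <- 0.4   # node 4 isolated
  g <- patch_graph(areas = c(2, 3, 1, 1.5), p = p, A_L = 20)
  for (index in c("PC", "IIC")) {
    ni <- node_importance(g, index)
    expect_equal(ni$dX[4], ni$intra[4], tolerance = 1e-9)
    expect_equal(ni$connector[4], 0, tolerance = 1e-9)
  }
})

test_that("a pure stepping stone's importance is carried by the connector fraction", {
  # tiny middle patch on the only route between two big patches
  g <- chain3(0.8, 0.8, areas = c(5, 0.01, 5), A_L = 20)
  ni <- node_importance(g, "PC")
  expect_gt(ni$connector[2], 0.9 * ni$dX[2])
  expect_gt(ni$connector[2], ni$connector[1])
  expect_gt(ni$connector[2], ni$connector[3])
})

test_that("stepping-stone value peaks at short dispersal and fades as D grows", {
  # three patches in a chain, probabilities derived from distances
  # the middle patch is wide: crossing it is free in the graph model, so
  # the direct 1-3 cost distance (around or through, paying resistance)
  # exceeds d12 + d23 and the two-step product can win
  d <- matrix(0, 3, 3)
  d[1, 2] <- d[2, 1] <- 40000
  d[2, 3] <- d[3, 2] <- 40000
  d[1, 3] <- d[3, 1] <- 100000
  conn_mid <- vapply(c(50000, 400000), function(D) {
    g <- patch_graph(areas = c(3, 1, 3), d = d, A_L = 20, D = D)
    node_importance(g, "PC")$connector[2]
  }, 0)
  expect_gt(conn_mid[1], conn_mid[2])  # long-D world needs no stepping stone
  g_short <- patch_graph(areas = c(3, 1, 3), d = d, A_L = 20, D = 50000)
  ni <- node_importance(g_short, "PC")
  expect_gt(ni$connector[2], ni$connector[1])
  expect_gt(ni$connector[2], ni$connector[3])
})

test_that("PC never decreases when a dispersal probability rises, nor IIC when a link is added", {
  set.seed(77)
  p <- random_p_matrix(5)
  areas <- runif(5, 1, 4)
  g <- patch_graph(areas = areas, p = p, A_L = 30)
  base_pc <- compute_pc(g)
  p2 <- p
  p2[1, 3] <- p2[3, 1] <- min(1, max(p[1, 3], 0.01) + 0.3)
  expect_gte(compute_pc(patch_graph(areas = areas, p = p2, A_L = 30)),
             base_pc - 1e-12)
  links <- p > 0; diag(links) <- FALSE
  gi <- patch_graph(areas = areas, p = p, links = links, A_L = 30)
  base_iic <- compute_iic(gi)
  links2 <- links
  off <- which(!links & upper.tri(links), arr.ind = TRUE)[1, ]
  links2[off[1], off[2]] <- links2[off[2], off[1]] <- TRUE
  expect_gte(compute_iic(patch_graph(areas = areas, p = p, links = links2,
                                     A_L = 30)), base_iic - 1e-12)
})

test_that("cross-scenario ranking averages dX with absent patches as zero and breaks ties by id", {
  ni1 <- structure(data.frame(id = c(1, 2, 3), dX = c(10, 30, 20)),
                   class = c("node_importance", "data.frame"))
  ni2 <- structure(data.frame(id = c(1, 2), dX = c(30, 10)),
                   class = c("node_importance", "data.frame"))
  rk <- rank_cores(list(s1 = ni1, s2 = ni2))
  expect_equal(rk$id[rk$rank == 1], 1)          # (10+30)/2 = 20
  expect_equal(rk$mean_dX[rk$id == 3], 10)      # (20 + 0)/2: absent -> 0
  # reversed orders with equal magnitudes: tie broken by id
  nia <- structure(data.frame(id = 1:2, dX = c(5, 8)),
                   class = c("node_importance", "data.frame"))
  nib <- structure(data.frame(id = 1:2, dX = c(8, 5)),
                   class = c("node_importance", "data.frame"))
  rk2 <- rank_cores(list(a = nia, b = nib))
  expect_equal(rk2$id, c(1, 2))
  # single scenario: ranking equals that scenario's order
  rk1 <- rank_cores(list(only = ni1))
  expect_equal(rk1$id, c(2, 3, 1))
})

test_that("patch graphs built from rasters use boundary-to-boundary cost distances", {
  # two 1-cell patches 3 cells apart on uniform resistance 2
  m <- matrix(0, 3, 5); m[2, 1] <- 10; m[2, 5] <- 10
  k <- raster_layer(m, grid_spec(3, 5, 1000))
  patches <- delineate_cores(k, 0.25)
  res <- raster_layer(2, grid_spec(3, 5, 1000))
  g <- build_patch_graph(patches, res, D = 16000, p_at_D = 0.5)
  expect_equal(g$d[1, 2], 8000)  # 4 steps * mean resistance 2 * 1000 m
  expect_equal(g$p[1, 2], exp(log(0.5) * 8000 / 16000))
  expect_true(g$links[1, 2])
  expect_equal(g$A_L, 15)        # defaults to full grid area in km^2
})
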