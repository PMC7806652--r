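# Independent oracles and fixture builders shared across the suite.
# Everything here is deliberately naive: exhaustive search with bound
# pruning, direct enumeration, closed forms. None of it calls the code
# paths it checks.

# Exhaustive least-cost search on a tiny resistance matrix: explores
# every improving simple path depth-first (a path is abandoned only once
# it can no longer improve the best known cost at its head, which never
# discards an optimal path). Returns the vector of minimal accumulated
# costs from `start` (row-major cell id) to every cell.
bf_cost_distance <- function(resvals, cell_size, start) {
  nr <- nrow(resvals); nc <- ncol(resvals)
  n <- nr * nc
  id <- function(r, c) (r - 1L) * nc + c
  nbrs <- vector("list", n)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(resvals[r, c])) next
    acc <- NULL
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (is.na(resvals[r2, c2])) next
      w <- (resvals[r, c] + resvals[r2, c2]) / 2 * cell_size *
        (if (dr != 0 && dc != 0) sqrt(2) else 1)
      acc <- rbind(acc, c(id(r2, c2), w))
    }
    nbrs[[id(r, c)]] <- acc
  }
  best <- rep(Inf, n)
  best[start] <- 0
  dfs <- function(v, cost) {
    for (k in seq_len(NROW(nbrs[[v]]))) {
      u <- nbrs[[v]][k, 1]; w <- nbrs[[v]][k, 2]
      if (cost + w < best[u] - 1e-9) {
        best[u] <<- cost + w
        dfs(u, cost + w)
      }
    }
  }
  dfs(start, 0)
  best
}

# All simple paths between i and j in an n-node graph given a logical
# adjacency matrix; calls `visit(path)` for each path (vector of nodes).
enum_simple_paths <- function(adj, i, j, visit) {
  n <- nrow(adj)
  path <- i
  used <- rep(FALSE, n); used[i] <- TRUE
  rec <- function(v) {
    if (v == j) { visit(path); return(invisible()) }
    for (u in which(adj[v, ])) {
      if (used[u]) next
      used[u] <<- TRUE; path <<- c(path, u)
      rec(u)
      used[u] <<- FALSE; path <<- path[-length(path)]
    }
  }
  rec(i)
}

# Minimum number of links between i and j over the binary link graph
# (Inf if disconnected), by enumeration.
bf_nl <- function(links, i, j) {
  if (i == j) return(0)
  best <- Inf
  enum_simple_paths(links, i, j, function(p)
    best <<- min(best, length(p) - 1))
  best
}

# Maximum product of probabilities over all simple paths (0 if none).
bf_pstar <- function(p, i, j) {
  if (i == j) return(1)
  adj <- p > 0; diag(adj) <- FALSE
  best <- 0
  enum_simple_paths(adj, i, j, function(path)
    best <<- max(best, prod(p[cbind(path[-length(path)], path[-1])])))
  best
}

bf_iic <- function(areas, links, A_L) {
  n <- length(areas)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    nl <- bf_nl(links, i, j)
    if (is.finite(nl)) tot <- tot + areas[i] * areas[j] / (1 + nl)
  }
  tot / A_L^2
}

bf_pc <- function(areas, p, A_L) {
  n <- length(areas)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    tot <- tot + areas[i] * areas[j] * bf_pstar(p, i, j)
  tot / A_L^2
}

# Mean lag-1 autocorrelation (horizontal and vertical) of a raster.
lag1_autocorr <- function(raster) {
  v <- raster$values
  (stats::cor(as.vector(v[, -1]), as.vector(v[, -ncol(v)])) +
     stats::cor(as.vector(v[-1, ]), as.vector(v[-nrow(v), ]))) / 2
}

# Random symmetric probability matrix on n nodes with a given density
# of positive entries; diagonal 1.
random_p_matrix <- function(n, density = 0.6) {
  p <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (stats::runif(1) < density) {
      v <- stats::runif(1, 0.05, 0.95)
      p[i, j] <- p[j, i] <- v
    }
  }
  diag(p) <- 1
  p
}

# Seeded synthetic landscape used by the fragmentation / prioritization
# fixtures: true suitability at the 8 km scale on a 64 km square, with
# its rarefied presence points and resistance surface.
fixture_landscape <- function() {
  grid <- grid_spec(64, 64, 1000)
  covs <- stats::setNames(
    lapply(1:3, function(i) generate_covariate_field(grid, 4000, 40 + i)),
    paste0("cov", 1:3))
  truth <- generate_true_suitability(covs, c(3, -3, 2), 8000)
  pres <- spatial_rarefy(sample_occurrences(truth, 60, 47), 5000)
  res <- suitability_to_resistance(truth$suitability)
  list(grid = grid, covariates = covs, truth = truth, presences = pres,
       resistance = res, A_L = 64 * 64)
}

# One replicate of the scale-recovery experiment: synthetic truth at
# true_scale, full prep + multi-scale evaluation, returns the scale the
# pipeline selects.
recover_scale_once <- function(seed, n = 256, autocorr_range = 4000,
                               coefficients = c(3, -3, 2),
                               true_scale = 8000, n_presences = 300,
                               n_absences = 1000,
                               scales_m = c(1, 2, 4, 8, 16, 32) * 1000,
                               learner = learner_spec("logistic")) {
  grid <- grid_spec(n, n, 1000)
  covs <- stats::setNames(
    lapply(1:3, function(i)
      generate_covariate_field(grid, autocorr_range, seed * 10 + i)),
    paste0("cov", 1:3))
  truth <- generate_true_suitability(covs, coefficients, true_scale)
  pres <- spatial_rarefy(sample_occurrences(truth, n_presences,
                                            seed * 10 + 7), 5000)
  abs <- sample_pseudo_absences(grid, pres, 5000, n_absences, seed * 10 + 8)
  pts <- occurrence_set(rbind(as.data.frame(pres),
                              transform(as.data.frame(abs),
                                        id = id + nrow(pres))))
  tab <- build_feature_table(pts, covs, scales_m)
  ev <- evaluate_scales(tab, names(covs), learner, k = 5, seed = seed)
  select_scale(ev)
}
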