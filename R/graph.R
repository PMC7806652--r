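#' Build the patch connectivity graph
#'
#' Nodes are core patches with their areas; edges carry the minimum
#' accumulated cost distance between patch boundaries (multi-source
#' Dijkstra from all cells of one patch to the nearest cell of the
#' other). Dispersal probabilities decay exponentially with cost
#' distance, `p_ij = exp(-k d_ij)`, with `k` calibrated so that
#' `p = p_at_D` exactly at the scenario's dispersal threshold `D`;
#' binary links join patches with `d_ij <= D`.
#'
#' @param patches A `patch_set` with at least one patch.
#' @param resistance The `resistance_surface` the patches live on.
#' @param D Dispersal cost threshold of the scenario (> 0), cost units.
#' @param p_at_D Dispersal probability assigned at distance `D`
#'   (in (0, 1); default 0.5, with 0.05 the usual conservative
#'   alternative).
#' @param landscape_area_km2 Total landscape area `A_L` used to
#'   normalize the connectivity indices; defaults to the full grid area.
#' @return An object of class `patch_graph`: list with `ids`, `areas`
#'   (km^2), `d` (cost-distance matrix, `Inf` if unreachable), `p`
#'   (probability matrix, 1 on the diagonal), `links` (logical matrix),
#'   `A_L`, `D`, `p_at_D`, `k`.
#' @export
build_patch_graph <- function(patches, resistance, D, p_at_D = 0.5,
                              landscape_area_km2 = NULL) {
  if (nrow(patches$table) < 1) stop("need at least one patch")
  if (!is.finite(D) || D <= 0) stop("D must be > 0")
  if (p_at_D <= 0 || p_at_D >= 1) stop("p_at_D must be in (0, 1)")
  g <- resistance$grid
  if (is.null(landscape_area_km2))
    landscape_area_km2 <- g$n_rows * g$n_cols * (g$cell_size / 1000)^2
  ids <- patches$table$id
  n <- length(ids)
  rg <- resistance_graph(resistance)
  cells <- lapply(ids, function(i) patch_cells(patches, i))
  d <- matrix(0, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1L)) {
      cd <- multi_source_cost(rg, cells[[i]])
      for (j in (i + 1L):n) {
        dij <- min(cd[cells[[j]]])
        d[i, j] <- d[j, i] <- dij
      }
    }
  }
  kdec <- -log(p_at_D) / D
  p <- exp(-kdec * d)
  p[!is.finite(d)] <- 0
  diag(p) <- 1
  links <- d <= D & is.finite(d)
  diag(links) <- FALSE
  structure(list(ids = ids, areas = patches$table$area_km2, d = d, p = p,
                 links = links, A_L = landscape_area_km2, D = D,
                 p_at_D = p_at_D, k = kdec),
            class = "patch_graph")
}

#' Construct a patch graph directly from attributes
#'
#' Assembles a `patch_graph` from explicit areas and either pairwise
#' distances or probabilities, for analyses and tests that do not start
#' from rasters.
#'
#' @param areas Patch areas (km^2).
#' @param d Optional symmetric cost-distance matrix.
#' @param p Optional symmetric probability matrix (built from `d` if
#'   omitted).
#' @param links Optional logical link matrix (built from `d <= D` if
#'   omitted).
#' @param A_L Landscape area (km^2).
#' @param D Dispersal threshold (cost units); required when derived
#'   quantities are built from `d`.
#' @param p_at_D Probability at distance `D` (default 0.5).
#' @param ids Optional patch ids (default `1:n`).
#' @return A `patch_graph`.
#' @export
patch_graph <- function(areas, d = NULL, p = NULL, links = NULL, A_L,
                        D = NA_real_, p_at_D = 0.5, ids = seq_along(areas)) {
  n <- length(areas)
  kdec <- if (is.finite(D)) -log(p_at_D) / D else NA_real_
  if (is.null(p)) {
    stopifnot(!is.null(d), is.finite(D))
    p <- exp(-kdec * d); p[!is.finite(d)] <- 0; diag(p) <- 1
  }
  if (is.null(links)) {
    links <- if (!is.null(d) && is.finite(D)) d <= D & is.finite(d)
    else p > 0
    diag(links) <- FALSE
  }
  if (is.null(d)) d <- matrix(NA_real_, n, n)
  structure(list(ids = ids, areas = areas, d = d, p = p,
                 links = links, A_L = A_L, D = D, p_at_D = p_at_D, k = kdec),
            class = "patch_graph")
}

## Topological shortest-path link counts over the binary link graph
## (Inf where unreachable).
nl_matrix <- function(g) {
  n <- length(g$areas)
  gr <- igraph::graph_from_adjacency_matrix(g$links * 1, mode = "undirected")
  igraph::distances(gr)
}

## Maximum product of probabilities over all paths: Dijkstra on -log(p)
## over edges with p > 0 (diagonal 1).
pstar_matrix <- function(g) {
  n <- length(g$areas)
  p <- g$p; diag(p) <- 0
  w <- -log(p)
  adj <- is.finite(w)
  gr <- igraph::graph_from_adjacency_matrix(adj * 1, mode = "undirected")
  el <- igraph::as_edgelist(gr)
  wts <- w[el]
  dist <- igraph::distances(gr, weights = wts)
  ps <- exp(-dist)
  diag(ps) <- 1
  ps
}

#' Integral index of connectivity (IIC)
#'
#' `IIC = sum_ij a_i a_j / (1 + nl_ij) / A_L^2`, where `nl_ij` is the
#' number of links in the shortest topological path between patches i
#' and j over the binary link graph (`nl_ii = 0`); unreachable pairs
#' contribute 0.
#'
#' @param g A `patch_graph`.
#' @return IIC in (0, 1\] for a non-empty graph; 0 for an empty one.
#' @export
compute_iic <- function(g) {
  if (length(g$areas) == 0) return(0)
  if (g$A_L <= 0) stop("A_L must be > 0")
  nl <- nl_matrix(g)
  term <- outer(g$areas, g$areas) / (1 + nl)  # Inf nl -> term 0
  term[!is.finite(nl)] <- 0
  sum(term) / g$A_L^2
}

#' Probability of connectivity (PC)
#'
#' `PC = sum_ij a_i a_j p*_ij / A_L^2`, where `p*_ij` is the maximum
#' product of dispersal probabilities over all paths between patches i
#' and j (`p*_ii = 1`), found by a shortest-path search under
#' `-log(p)` edge weights.
#'
#' @param g A `patch_graph`.
#' @return PC in (0, 1\] for a non-empty graph; 0 for an empty one.
#' @export
compute_pc <- function(g) {
  if (length(g$areas) == 0) return(0)
  if (g$A_L <= 0) stop("A_L must be > 0")
  ps <- pstar_matrix(g)
  sum(outer(g$areas, g$areas) * ps) / g$A_L^2
}

## patch_graph with node k removed
drop_node <- function(g, k) {
  keep <- setdiff(seq_along(g$areas), k)
  structure(list(ids = g$ids[keep], areas = g$areas[keep],
                 d = g$d[keep, keep, drop = FALSE],
                 p = g$p[keep, keep, drop = FALSE],
                 links = g$links[keep, keep, drop = FALSE],
                 A_L = g$A_L, D = g$D, p_at_D = g$p_at_D, k = g$k),
            class = "patch_graph")
}

#' Node-removal importance with intra/flux/connector decomposition
#'
#' For each patch k, `dX_k = 100 (X - X_without_k) / X` is the percentage
#' loss of the index when the patch is removed. It decomposes into:
#' `intra` (`100 a_k^2 / (X A_L^2)`, the patch's own internal
#' connectivity), `flux` (`100 * 2 sum_{j != k} a_k a_j w_kj / (X A_L^2)`,
#' its dispersal exchange with all other patches, with `w = p*` for PC
#' and `1/(1+nl)` for IIC), and `connector = dX - intra - flux`, the part
#' owed purely to the patch's topological role as a stepping stone.
#'
#' @param g A `patch_graph`.
#' @param index `"PC"` or `"IIC"`.
#' @return Data frame of class `node_importance`: columns `id`, `dX`,
#'   `intra`, `flux`, `connector` (all percentages), plus attribute
#'   `index_value` (the intact X).
#' @export
node_importance <- function(g, index = c("PC", "IIC")) {
  index <- match.arg(index)
  n <- length(g$areas)
  if (n == 0) stop("graph is empty")
  compute <- if (index == "PC") compute_pc else compute_iic
  X <- compute(g)
  if (X <= 0) stop("undefined importance: index value is 0")
  w <- if (index == "PC") pstar_matrix(g) else {
    nl <- nl_matrix(g)
    wi <- 1 / (1 + nl)
    wi[!is.finite(nl)] <- 0
    wi
  }
  out <- do.call(rbind, lapply(seq_len(n), function(k) {
    Xk <- if (n == 1) 0 else compute(drop_node(g, k))
    dX <- 100 * (X - Xk) / X
    intra <- 100 * g$areas[k]^2 / (X * g$A_L^2)
    flux <- 100 * 2 * sum(g$areas[k] * g$areas[-k] * w[k, -k]) /
      (X * g$A_L^2)
    data.frame(id = g$ids[k], dX = dX, intra = intra, flux = flux,
               connector = dX - intra - flux)
  }))
  attr(out, "index_value") <- X
  attr(out, "index") <- index
  class(out) <- c("node_importance", "data.frame")
  out
}

#' Rank core patches by mean importance across dispersal scenarios
#'
#' Averages each patch's importance over the scenarios (a patch absent
#' from a scenario, e.g. fragmented away, contributes 0 for that
#' scenario) and ranks in descending order of the mean, ties broken by
#' ascending patch id.
#'
#' @param importances Named list of `node_importance` data frames, one
#'   per dispersal scenario.
#' @return Data frame of class `scenario_table`: `id`, one `dX_<name>`
#'   column per scenario, `mean_dX`, `rank`.
#' @export
rank_cores <- function(importances) {
  if (length(importances) < 1) stop("need at least one scenario")
  if (is.null(names(importances)) || any(names(importances) == ""))
    names(importances) <- paste0("scenario", seq_along(importances))
  all_ids <- sort(unique(unlist(lapply(importances, `[[`, "id"))))
  cols <- lapply(importances, function(im) {
    v <- stats::setNames(rep(0, length(all_ids)), all_ids)
    v[as.character(im$id)] <- im$dX
    v
  })
  m <- do.call(cbind, cols)
  colnames(m) <- paste0("dX_", names(importances))
  mean_dX <- rowMeans(m)
  ord <- order(-mean_dX, all_ids)
  out <- data.frame(id = all_ids, m, mean_dX = mean_dX,
                    check.names = FALSE)[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("scenario_table", "data.frame")
  out
}

#' Write a patch graph in the Conefor two-file layout
#'
#' Node file: `id area` pairs; connection file: `id_i id_j distance`
#' triples (finite distances only), both whitespace-separated without
#' headers.
#'
#' @param g A `patch_graph`.
#' @param node_path,connection_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_conefor <- function(g, node_path, connection_path) {
  utils::write.table(data.frame(g$ids, g$areas), node_path,
                     row.names = FALSE, col.names = FALSE)
  n <- length(g$ids)
  pairs <- which(upper.tri(g$d) & is.finite(g$d), arr.ind = TRUE)
  utils::write.table(data.frame(g$ids[pairs[, 1]], g$ids[pairs[, 2]],
                                g$d[pairs]),
                     connection_path, row.names = FALSE, col.names = FALSE)
  invisible(c(node_path, connection_path))
}
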