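#' Assemble and validate a pipeline configuration
#'
#' Merges user settings over the package defaults and validates them.
#' The defaults carry the analysis conventions used throughout: a 5 km
#' rarefaction/exclusion radius, 1000 pseudo-absences, candidate scales
#' of 1-32 km, dispersal cost thresholds of 50,000-400,000 cost units,
#' a 25% fraction-of-maximum core cutoff and a 0.5
#' distance-probability anchor. Seeds are mandatory: nothing in the
#' pipeline falls back to clock seeding.
#'
#' @param ... Named settings overriding the defaults, or a single list
#'   of such settings.
#' @param yaml_path Optional path to a YAML file of settings (applied
#'   before `...`).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(..., yaml_path = NULL) {
  defaults <- list(
    n_rows = 128, n_cols = 128, cell_size = 1000,
    n_covariates = 3, autocorr_range = 4000,
    coefficients = c(3, -3, 2), true_scale = 8000,
    n_presences = 208, n_protected = 4, road_spacing = 15000,
    rarefy_radius = 5000, n_absences = 1000, exclusion_radius = 5000,
    scales_km = c(1, 2, 4, 8, 16, 32),
    vif_threshold = 3, corr_cut = 0.7, cv_folds = 5,
    learner = "rf", num_trees = 500,
    resistance_base = 1000, rmin = 1, rmax = 10,
    thresholds = c(50000, 100000, 200000, 300000, 400000),
    rel_core_threshold = 0.25, core_mode = "max_fraction",
    p_at_D = 0.5, buffer_cells = 1,
    seed = NULL)
  user <- list(...)
  if (length(user) == 1L && is.null(names(user)) && is.list(user[[1]]))
    user <- user[[1]]
  cfg <- defaults
  if (!is.null(yaml_path)) {
    yml <- yaml::read_yaml(yaml_path)
    cfg[names(yml)] <- yml
  }
  cfg[names(user)] <- user
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$seed) || !is.finite(cfg$seed))
    stop("config must set an integer seed (no clock seeding)")
  if (length(cfg$thresholds) == 0)
    stop("thresholds must be a non-empty ascending list")
  if (is.unsorted(cfg$thresholds, strictly = TRUE))
    stop("thresholds must be sorted in ascending order")
  if (any(cfg$thresholds <= 0)) stop("thresholds must be positive")
  if (cfg$rel_core_threshold <= 0 || cfg$rel_core_threshold >= 1)
    stop("rel_core_threshold must be in (0, 1)")
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Write a pipeline configuration to YAML
#'
#' @param config A `pipeline_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

stage_log <- function(quiet, stage, fmt, ...) {
  if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: synthetic landscape generation (covariates, true
#' suitability, presence points, protected-area and road overlays) ->
#' occurrence preparation (spatial rarefaction, pseudo-absences) ->
#' multi-scale suitability modeling with collinearity screening and
#' AUC/TSS scale selection -> suitability-to-resistance transform ->
#' cumulative resistant kernels at every dispersal threshold plus the
#' factorial least-cost-path corridor surface -> core-patch delineation,
#' protected-area/road overlays and class-level fragmentation metrics
#' per threshold -> patch-graph prioritization (dPC and dIIC with
#' intra/flux/connector fractions) and cross-scenario ranking.
#'
#' Every stage is logged with its parameters; all randomness derives
#' from `config$seed`, so a config reproduces its outputs exactly.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, CSV report tables
#'   (model evaluation by scale, per-threshold core overlay statistics,
#'   corridor overlay statistics, class metrics by threshold, importance
#'   and ranking tables), `.asc` rasters and point/overlay files are
#'   written there.
#' @param quiet Suppress stage logging.
#' @return Invisibly, a list with every intermediate object: `truth`,
#'   `covariates`, `overlays`, `presences`, `absences`, `scale_eval`,
#'   `selected_scale`, `model`, `suitability`, `resistance`, `kernels`,
#'   `corridor`, `cores`, `core_overlays`, `corridor_overlay`,
#'   `class_metrics`, `importance`, `ranking`, `tables`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  grid <- grid_spec(cfg$n_rows, cfg$n_cols, cfg$cell_size)
  A_L <- cfg$n_rows * cfg$n_cols * (cfg$cell_size / 1000)^2

  ## synth ------------------------------------------------------------
  stage_log(quiet, "synth",
            "grid %dx%d @ %gm, %d covariates (range %gm), true scale %gm, seed %d",
            cfg$n_rows, cfg$n_cols, cfg$cell_size, cfg$n_covariates,
            cfg$autocorr_range, cfg$true_scale, cfg$seed)
  covariates <- stats::setNames(
    lapply(seq_len(cfg$n_covariates), function(i)
      generate_covariate_field(grid, cfg$autocorr_range,
                               seed = cfg$seed + i)),
    paste0("cov", seq_len(cfg$n_covariates)))
  truth <- generate_true_suitability(covariates, cfg$coefficients,
                                     cfg$true_scale, seed = cfg$seed)
  presences_raw <- sample_occurrences(truth, cfg$n_presences,
                                      seed = cfg$seed + 101)
  overlays <- generate_overlays(grid, cfg$n_protected, cfg$road_spacing,
                                seed = cfg$seed + 202)

  ## prep -------------------------------------------------------------
  presences <- spatial_rarefy(presences_raw, cfg$rarefy_radius)
  stage_log(quiet, "prep", "rarefied %d -> %d presences (radius %gm)",
            nrow(presences_raw), nrow(presences), cfg$rarefy_radius)
  absences <- sample_pseudo_absences(grid, presences, cfg$exclusion_radius,
                                     cfg$n_absences, seed = cfg$seed + 303)
  stage_log(quiet, "prep", "%d pseudo-absences (exclusion %gm)",
            nrow(absences), cfg$exclusion_radius)
  pts <- occurrence_set(rbind(as.data.frame(presences),
                              transform(as.data.frame(absences),
                                        id = id + nrow(presences))))

  ## sdm --------------------------------------------------------------
  scales_m <- cfg$scales_km * 1000
  learner <- learner_spec(cfg$learner, num_trees = cfg$num_trees)
  table <- build_feature_table(pts, covariates, scales_m)
  stage_log(quiet, "sdm", "feature table %d x %d over scales {%s} km",
            nrow(table), ncol(table) - 1,
            paste(cfg$scales_km, collapse = ","))
  evals <- evaluate_scales(table, names(covariates), learner,
                           k = cfg$cv_folds, seed = cfg$seed + 404,
                           per_variable = TRUE)
  sel <- select_scale(evals)
  stage_log(quiet, "sdm", "selected scale %g km (CV AUC %.3f)",
            sel / 1000, evals$auc[evals$scale_m == sel])
  sel_cols <- scale_col(names(covariates), sel)
  sel_table <- table[, c("label", sel_cols), drop = FALSE]
  attr(sel_table, "scales_m") <- sel
  sel_table <- vif_screen(sel_table, cfg$vif_threshold, cfg$corr_cut)
  model <- fit_suitability(sel_table, learner, seed = cfg$seed + 505)
  suitability <- predict_surface(model, covariates)

  ## resist -----------------------------------------------------------
  resistance <- suitability_to_resistance(suitability, cfg$resistance_base,
                                          cfg$rmin, cfg$rmax)
  stage_log(quiet, "resist", "base %g, range [%g, %g]",
            cfg$resistance_base, cfg$rmin, cfg$rmax)

  ## connect ----------------------------------------------------------
  kernels <- lapply(cfg$thresholds, function(D) {
    stage_log(quiet, "connect", "resistant kernel, D = %g cost units", D)
    resistant_kernel(resistance, presences, D)
  })
  names(kernels) <- as.character(cfg$thresholds)
  corridor <- factorial_lcp(resistance, presences,
                            buffer_radius = cfg$buffer_cells * cfg$cell_size)
  stage_log(quiet, "connect", "factorial LCP over %d pairs", corridor$n_pairs)

  ## cores ------------------------------------------------------------
  cores <- lapply(kernels, delineate_cores,
                  rel_threshold = cfg$rel_core_threshold,
                  mode = cfg$core_mode)
  core_overlays <- lapply(cores, overlay_stats,
                          protected = overlays$protected,
                          roads = overlays$roads)
  corridor_overlay <- overlay_stats(corridor, overlays$protected,
                                    overlays$roads)
  cm <- lapply(cores, class_metrics, landscape_area_km2 = A_L)
  for (D in names(cores))
    stage_log(quiet, "cores", "D = %s: NP %d, PLAND %.2f%%", D,
              cm[[D]]$np, cm[[D]]$pland)

  ## rank -------------------------------------------------------------
  importance <- list()
  for (D in names(cores)) {
    if (nrow(cores[[D]]$table) == 0) next
    pg <- build_patch_graph(cores[[D]], resistance,
                            D = as.numeric(D), p_at_D = cfg$p_at_D,
                            landscape_area_km2 = A_L)
    importance[[D]] <- list(PC = node_importance(pg, "PC"),
                            IIC = node_importance(pg, "IIC"))
  }
  ranking <- if (length(importance)) {
    list(PC = rank_cores(lapply(importance, `[[`, "PC")),
         IIC = rank_cores(lapply(importance, `[[`, "IIC")))
  } else NULL
  stage_log(quiet, "rank", "importance computed for %d scenario(s)",
            length(importance))

  ## report tables -----------------------------------------------------
  model_tab <- as.data.frame(t(as.matrix(
    evals[, c("auc", "tss")])))
  colnames(model_tab) <- sprintf("%gkm", evals$scale_m / 1000)
  rownames(model_tab) <- c("AUC", "TSS")
  core_tab <- do.call(rbind, lapply(names(core_overlays), function(D) {
    tot <- core_overlays[[D]][core_overlays[[D]]$id == "total", ]
    if (nrow(tot) == 0)
      tot <- data.frame(extent_km2 = 0, protected_km2 = 0,
                        protected_pct = 0, road_length_m = 0,
                        road_density_m_per_km2 = 0)
    data.frame(threshold = as.numeric(D),
               extent_km2 = tot$extent_km2,
               protected_km2 = tot$protected_km2,
               protected_pct = tot$protected_pct,
               road_density_m_per_km2 = tot$road_density_m_per_km2)
  }))
  corr_tot <- corridor_overlay[corridor_overlay$id == "total", ]
  corridor_tab <- data.frame(
    extent_km2 = corr_tot$extent_km2,
    protected_km2 = corr_tot$protected_km2,
    protected_pct = corr_tot$protected_pct,
    road_crossing_km = corr_tot$road_length_m / 1000,
    road_density_m_per_km2 = corr_tot$road_density_m_per_km2)
  metrics_tab <- do.call(rbind, lapply(names(cm), function(D)
    data.frame(threshold = as.numeric(D), np = cm[[D]]$np,
               lpi = cm[[D]]$lpi, pland = cm[[D]]$pland,
               gyrate_am_m = cm[[D]]$gyrate_am)))
  tables <- list(model_eval = model_tab, core_overlays = core_tab,
                 corridor_overlay = corridor_tab, class_metrics = metrics_tab)

  if (!is.null(out_dir)) {
    wp <- function(x, f) utils::write.csv(x, file.path(out_dir, f),
                                          row.names = f == "model_eval.csv")
    wp(model_tab, "model_eval.csv")
    wp(core_tab, "core_overlays.csv")
    wp(corridor_tab, "corridor_overlay.csv")
    wp(metrics_tab, "class_metrics.csv")
    if (length(importance)) {
      imp_tab <- do.call(rbind, lapply(names(importance), function(D)
        do.call(rbind, lapply(c("PC", "IIC"), function(ix)
          cbind(threshold = as.numeric(D), index = ix,
                as.data.frame(importance[[D]][[ix]]))))))
      wp(imp_tab, "importance.csv")
      wp(ranking$PC, "ranking_pc.csv")
      wp(ranking$IIC, "ranking_iic.csv")
    }
    write_asc(suitability, file.path(out_dir, "suitability.asc"))
    write_asc(resistance, file.path(out_dir, "resistance.asc"))
    for (D in names(kernels))
      write_asc(kernels[[D]]$k, file.path(out_dir, sprintf("kernel_%s.asc", D)))
    write_asc(corridor$c, file.path(out_dir, "corridor.asc"))
    write_points_csv(pts, file.path(out_dir, "occurrences.csv"))
    write_polygons_geojson(overlays$protected,
                           file.path(out_dir, "protected.geojson"))
    write_polylines_geojson(overlays$roads, file.path(out_dir, "roads.geojson"))
    write_config(cfg, file.path(out_dir, "config.yaml"))
  }

  invisible(list(config = cfg, grid = grid, covariates = covariates,
                 truth = truth, overlays = overlays,
                 presences = presences, absences = absences,
                 scale_eval = evals, selected_scale = sel, model = model,
                 suitability = suitability, resistance = resistance,
                 kernels = kernels, corridor = corridor, cores = cores,
                 core_overlays = core_overlays,
                 corridor_overlay = corridor_overlay, class_metrics = cm,
                 importance = importance, ranking = ranking,
                 tables = tables))
}
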