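#' Build a multi-scale feature table
#'
#' For every covariate and every candidate scale, computes the circular
#' focal mean of the covariate at that radius and extracts it at each
#' occurrence record, yielding one column per (covariate, scale) named
#' `<covariate>_<km>km`. The label column is 1 for presence, 0 for
#' pseudo-absence.
#'
#' @param points An `occurrence_set` (presences and pseudo-absences).
#' @param covariates Named list of [raster_layer()]s on one grid.
#' @param scales_m Candidate focal radii in metres.
#' @return Data frame of class `feature_table` with attribute
#'   `scales_m`; columns `label` then covariate-by-scale features.
#' @export
build_feature_table <- function(points, covariates, scales_m) {
  stopifnot(length(covariates) >= 1, !is.null(names(covariates)))
  g <- covariates[[1]]$grid
  for (cv in covariates) stop_if_misaligned(cv, g, "covariate")
  out <- data.frame(label = as.integer(points$label == "presence"))
  for (nm in names(covariates)) {
    for (s in scales_m) {
      sm <- focal_mean(covariates[[nm]], s)
      out[[scale_col(nm, s)]] <- extract_values(sm, points$x, points$y)
    }
  }
  keep <- stats::complete.cases(out)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("feature_table", "data.frame"),
            scales_m = scales_m)
}

scale_col <- function(name, scale_m) sprintf("%s_%gkm", name, scale_m / 1000)

feature_matrix <- function(table) {
  as.matrix(table[, setdiff(names(table), "label"), drop = FALSE])
}

#' Variance inflation factors
#'
#' VIF of column j is `1 / (1 - R^2_j)` where `R^2_j` comes from the
#' ordinary least-squares regression of column j on all other columns.
#' An orthogonal design has VIF exactly 1 for every column.
#'
#' @param X Numeric matrix or data frame of predictors (no label).
#' @return Named numeric vector of VIFs (`Inf` for perfectly collinear
#'   columns, `NA` for constant columns).
#' @export
vif_values <- function(X) {
  X <- as.matrix(X)
  p <- ncol(X)
  out <- stats::setNames(rep(NA_real_, p), colnames(X))
  for (j in seq_len(p)) {
    yj <- X[, j]
    if (stats::sd(yj) == 0) next  # constant: VIF undefined
    if (p == 1L) { out[j] <- 1; next }
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), yj)
    r2 <- 1 - sum(fit$residuals^2) / sum((yj - mean(yj))^2)
    out[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  out
}

#' Collinearity screen by pairwise correlation and iterative VIF
#'
#' Removes predictors until the retained set has pairwise `|r| <=
#' corr_cut` and all VIF `<= threshold`. Removal is iterative, dropping
#' the worst offender each pass: first, while any pair exceeds the
#' correlation cut, the member of the worst pair with the larger mean
#' absolute correlation to everything else is dropped; then, while any
#' VIF exceeds the threshold, the column with the largest VIF is dropped.
#' Constant columns are removed up front with a warning (their VIF is
#' undefined).
#'
#' @param table A `feature_table` (label column is preserved) or a
#'   numeric matrix/data frame of predictors.
#' @param threshold Maximum allowed VIF (default 3).
#' @param corr_cut Maximum allowed absolute pairwise correlation
#'   (default 0.7).
#' @return The screened table, with attribute `vif` giving the VIFs of
#'   the retained predictors and attribute `dropped` naming removals.
#' @export
vif_screen <- function(table, threshold = 3, corr_cut = 0.7) {
  has_label <- "label" %in% colnames(table)
  X <- as.matrix(if (has_label)
    table[, setdiff(colnames(table), "label"), drop = FALSE] else table)
  if (ncol(X) < 2) stop("need at least 2 candidate columns")
  dropped <- character(0)
  const <- apply(X, 2, stats::sd) == 0
  if (any(const)) {
    warning(sprintf("removing constant column(s) with undefined VIF: %s",
                    paste(colnames(X)[const], collapse = ", ")))
    dropped <- c(dropped, colnames(X)[const])
    X <- X[, !const, drop = FALSE]
  }
  repeat {
    if (ncol(X) < 2) break
    cm <- abs(stats::cor(X)); diag(cm) <- 0
    if (max(cm) > corr_cut + 1e-12) {
      worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
      ms <- colMeans(abs(stats::cor(X)))
      drop_j <- worst[which.max(ms[worst])]
      dropped <- c(dropped, colnames(X)[drop_j])
      X <- X[, -drop_j, drop = FALSE]
      next
    }
    v <- vif_values(X)
    if (max(v) > threshold) {
      drop_j <- which.max(v)
      dropped <- c(dropped, colnames(X)[drop_j])
      X <- X[, -drop_j, drop = FALSE]
      next
    }
    break
  }
  keep <- colnames(X)
  out <- if (has_label) table[, c("label", keep), drop = FALSE]
  else table[, keep, drop = FALSE]
  attr(out, "vif") <- vif_values(X)
  attr(out, "dropped") <- dropped
  attr(out, "scales_m") <- attr(table, "scales_m")
  out
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a randomly chosen
#' presence scores higher than a randomly chosen absence, counting ties
#' as one half. Invariant under any strictly monotone transform of the
#' scores.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (1/TRUE/"presence" = positive).
#' @return AUC in \[0, 1\].
#' @export
evaluate_auc <- function(scores, labels) {
  pos <- as_binary_labels(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels))
    as.character(labels) == "presence"
  else as.logical(labels)
}

#' True skill statistic
#'
#' Maximizes sensitivity + specificity - 1 over classification
#' thresholds, scanning the midpoints between consecutive sorted distinct
#' scores (plus outer thresholds), which finds the exact maximum. The
#' smallest maximizing threshold is returned on ties.
#'
#' @inheritParams evaluate_auc
#' @return List with `tss` (in \[-1, 1\]) and `threshold`.
#' @export
evaluate_tss <- function(scores, labels) {
  pos <- as_binary_labels(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop("TSS undefined: both classes must be present")
  s <- sort(unique(scores))
  cand <- if (length(s) == 1) s else
    c(s[1] - 1, (s[-1] + s[-length(s)]) / 2, s[length(s)] + 1)
  tss <- vapply(cand, function(t) {
    sens <- sum(pos & scores >= t) / n1
    spec <- sum(!pos & scores < t) / n0
    sens + spec - 1
  }, 0)
  best <- which.max(tss)  # which.max takes the first (smallest) on ties
  list(tss = tss[best], threshold = cand[best])
}

#' Learner specifications for suitability models
#'
#' A learner is a contract: `fit(x, y, seed)` returning a handle and
#' `predict(handle, x)` returning continuous scores in \[0, 1\].
#' `"rf"` is an ensemble of randomized decision trees (a probability
#' random forest via \pkg{ranger}, single-threaded for reproducibility);
#' `"logistic"` is a plain binomial GLM, useful as a fast deterministic
#' baseline in tests.
#'
#' @param name `"rf"` or `"logistic"`.
#' @param num_trees Trees for the forest learner (default 500).
#' @return A list with elements `name`, `fit`, `predict`.
#' @export
learner_spec <- function(name = c("rf", "logistic"), num_trees = 500) {
  name <- match.arg(name)
  if (name == "rf") {
    list(name = "rf",
         fit = function(x, y, seed) {
           d <- data.frame(y = factor(y, levels = c(0, 1)), x,
                           check.names = FALSE)
           ranger::ranger(y ~ ., data = d, probability = TRUE,
                          num.trees = num_trees, seed = seed,
                          num.threads = 1)
         },
         predict = function(m, x) {
           p <- stats::predict(m, data.frame(x, check.names = FALSE),
                               num.threads = 1)$predictions
           unname(p[, "1"])
         })
  } else {
    list(name = "logistic",
         fit = function(x, y, seed) {
           d <- data.frame(y = y, x, check.names = FALSE)
           suppressWarnings(stats::glm(y ~ ., data = d, family = stats::binomial()))
         },
         predict = function(m, x) {
           unname(stats::predict(m, data.frame(x, check.names = FALSE),
                                 type = "response"))
         })
  }
}

#' Fit a suitability model
#'
#' Fits the learner on a (screened) feature table and returns a model
#' handle that predicts continuous suitability scores in \[0, 1\].
#' Deterministic given the seed.
#'
#' @param table A `feature_table` with a `label` column and at least one
#'   row of each class.
#' @param learner A [learner_spec()] (default the forest learner).
#' @param seed Integer seed passed to the learner.
#' @return An object of class `suitability_model` with elements `model`,
#'   `learner`, `features` (column names used), `seed`.
#' @export
fit_suitability <- function(table, learner = learner_spec("rf"), seed = 1) {
  y <- table$label
  if (length(unique(y)) < 2 || min(table(y)) < 2)
    stop("degenerate table: need at least two rows of each class")
  x <- feature_matrix(table)
  m <- learner$fit(x, y, seed)
  structure(list(model = m, learner = learner, features = colnames(x),
                 seed = seed),
            class = "suitability_model")
}

#' Predict suitability scores from a fitted model
#'
#' @param model A `suitability_model`.
#' @param newdata Data frame or matrix containing the model's feature
#'   columns.
#' @return Numeric scores in \[0, 1\].
#' @export
predict_suitability <- function(model, newdata) {
  x <- as.data.frame(newdata)[, model$features, drop = FALSE]
  p <- model$learner$predict(model$model, x)
  pmin(pmax(p, 0), 1)
}

#' Cross-validated model evaluation
#'
#' Stratified k-fold cross-validation: folds are assigned within each
#' class in seeded random order, out-of-fold scores are pooled, and AUC
#' and TSS are computed on the pooled scores. Training-set metrics are
#' reported alongside for transparency.
#'
#' @param table A `feature_table`.
#' @param learner A [learner_spec()].
#' @param k Number of folds (default 5).
#' @param seed Integer seed (fold assignment and learner).
#' @return List of class `model_eval`: `auc`, `tss`, `tss_threshold`
#'   (cross-validated), `train_auc`, `train_tss`.
#' @export
evaluate_model <- function(table, learner = learner_spec("rf"), k = 5,
                           seed = 1) {
  y <- table$label
  x <- feature_matrix(table)
  folds <- with_seed(seed, {
    f <- integer(length(y))
    for (cls in unique(y)) {
      i <- which(y == cls)
      f[i] <- sample(rep_len(seq_len(k), length(i)))
    }
    f
  })
  scores <- rep(NA_real_, length(y))
  for (fold in seq_len(k)) {
    tr <- folds != fold
    m <- learner$fit(x[tr, , drop = FALSE], y[tr], seed + fold)
    scores[!tr] <- learner$predict(m, x[!tr, , drop = FALSE])
  }
  full <- learner$fit(x, y, seed)
  train_scores <- learner$predict(full, x)
  cv_tss <- evaluate_tss(scores, y)
  structure(list(auc = evaluate_auc(scores, y),
                 tss = cv_tss$tss, tss_threshold = cv_tss$threshold,
                 train_auc = evaluate_auc(train_scores, y),
                 train_tss = evaluate_tss(train_scores, y)$tss),
            class = "model_eval")
}

#' Evaluate one suitability model per candidate scale
#'
#' For each scale, a multivariate model is fitted on that scale's columns
#' of the feature table and evaluated by cross-validation; results mirror
#' the usual AUC/TSS-by-scale model comparison table. Per-variable best
#' scales (the highest univariate cross-validated AUC for each covariate)
#' are recorded alongside, supporting the alternative workflow in which a
#' single model mixes each variable at its own best scale.
#'
#' @param table A `feature_table` built over `scales_m`.
#' @param covariate_names Names of the covariates in the table.
#' @param learner A [learner_spec()].
#' @param k Cross-validation folds.
#' @param seed Integer seed.
#' @param per_variable Also compute per-variable best scales (univariate
#'   models for every covariate at every scale); default `FALSE`.
#' @return Data frame of class `scale_eval` with one row per scale
#'   (columns `scale_m`, `auc`, `tss`, `tss_threshold`, `train_auc`,
#'   `train_tss`) and, if requested, attribute `best_scale_per_variable`.
#' @export
evaluate_scales <- function(table, covariate_names, learner = learner_spec("rf"),
                            k = 5, seed = 1, per_variable = FALSE) {
  scales_m <- attr(table, "scales_m")
  stopifnot(!is.null(scales_m))
  rows <- lapply(seq_along(scales_m), function(si) {
    s <- scales_m[si]
    cols <- scale_col(covariate_names, s)
    sub <- table[, c("label", intersect(cols, names(table))), drop = FALSE]
    attr(sub, "scales_m") <- s
    ev <- evaluate_model(sub, learner, k, seed + si)
    data.frame(scale_m = s, auc = ev$auc, tss = ev$tss,
               tss_threshold = ev$tss_threshold,
               train_auc = ev$train_auc, train_tss = ev$train_tss)
  })
  out <- do.call(rbind, rows)
  best_per_var <- if (!per_variable) NULL else vapply(covariate_names, function(nm) {
    aucs <- vapply(seq_along(scales_m), function(si) {
      col <- scale_col(nm, scales_m[si])
      if (!col %in% names(table)) return(NA_real_)
      sub <- table[, c("label", col), drop = FALSE]
      evaluate_model(sub, learner, k, seed + 100 + si)$auc
    }, 0)
    scales_m[which.max(aucs)]
  }, 0)
  structure(out, class = c("scale_eval", "data.frame"),
            best_scale_per_variable = best_per_var)
}

#' Select the operative scale from per-scale evaluations
#'
#' Picks the scale with the highest AUC; ties are broken by the highest
#' TSS, then by the smallest scale.
#'
#' @param evals A `scale_eval` data frame (or any data frame with
#'   `scale_m`, `auc`, `tss`).
#' @return Selected scale in metres.
#' @export
select_scale <- function(evals) {
  if (is.null(nrow(evals)) || nrow(evals) < 1)
    stop("need at least one evaluation")
  ord <- order(-evals$auc, -evals$tss, evals$scale_m)
  evals$scale_m[ord[1]]
}

#' Project a fitted model onto the landscape
#'
#' Builds the model's feature rasters (focal means of each covariate at
#' the scales encoded in the feature names), assembles the per-cell
#' feature matrix and predicts a suitability score for every valid cell.
#' Nodata propagates.
#'
#' @param model A `suitability_model`.
#' @param covariates Named list of [raster_layer()]s on one grid; names
#'   must match the covariates the model was trained on.
#' @return A [raster_layer()] with values in \[0, 1\] (class also
#'   `suitability_surface`), with attribute `provenance`.
#' @export
predict_surface <- function(model, covariates) {
  g <- covariates[[1]]$grid
  for (cv in covariates) stop_if_misaligned(cv, g, "covariate")
  feat <- list()
  for (fn in model$features) {
    m <- regmatches(fn, regexec("^(.*)_([0-9.]+)km$", fn))[[1]]
    if (length(m) != 3 || !m[2] %in% names(covariates))
      stop(sprintf("cannot resolve feature '%s' against covariates", fn))
    sm <- focal_mean(covariates[[m[2]]], as.numeric(m[3]) * 1000)
    feat[[fn]] <- values_rowmajor(sm)
  }
  X <- do.call(cbind, feat)
  ok <- stats::complete.cases(X)
  out <- rep(NA_real_, nrow(X))
  out[ok] <- predict_suitability(model, X[ok, , drop = FALSE])
  surf <- raster_from_rowmajor(out, g)
  class(surf) <- c("suitability_surface", class(surf))
  attr(surf, "provenance") <- list(learner = model$learner$name,
                                   features = model$features,
                                   seed = model$seed)
  surf
}
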