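test_that("focal mean matches the discrete-circle enumeration and edge contract", {
  g <- grid_spec(9, 9, 1000)
  # constant field is a fixed point at any radius
  const <- raster_layer(3.7, g)
  expect_equal(focal_mean(const, 2500)$values, const$values, tolerance = 1e-9)
  # single impulse, radius = 2 cells: 13-cell discrete circle
  m <- matrix(0, 9, 9); m[5, 5] <- 1
  f <- focal_mean(raster_layer(m, g), 2000)
  expect_equal(f$values[5, 5], 1 / 13, tolerance = 1e-9)
  expect_equal(f$values[5, 7], 1 / 13, tolerance = 1e-9)  # on the rim
  expect_equal(f$values[5, 8], 0, tolerance = 1e-9)       # beyond it
  # corner cell averages over the in-bounds window only: for radius 2
  # cells the corner window has 6 cells
  ones <- raster_layer(1, g)
  expect_equal(focal_mean(ones, 2000)$values[1, 1], 1, tolerance = 1e-9)
  impulse <- matrix(0, 9, 9); impulse[1, 1] <- 1
  fc <- focal_mean(raster_layer(impulse, g), 2000)
  expect_equal(fc$values[1, 1], 1 / 6, tolerance = 1e-9)
  # nodata cells are excluded from neighbours' means and stay nodata
  m2 <- matrix(1, 9, 9); m2[5, 5] <- NA
  fn <- focal_mean(raster_layer(m2, g), 2000)
  expect_true(is.na(fn$values[5, 5]))
  expect_equal(fn$values[5, 6], 1, tolerance = 1e-9)
  expect_error(focal_mean(ones, 100), "radius")
})

test_that("VIF matches its closed forms", {
  n <- 200
  set.seed(4)
  # centred orthonormal design: VIF exactly 1 per column (the columns
  # are orthogonalized against the intercept too)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))[, 2:4]
  colnames(Q) <- c("a", "b", "c")
  expect_equal(unname(vif_values(Q)), rep(1, 3), tolerance = 1e-9)
  # two columns with empirical r = 0.7 exactly: VIF = 1/(1-0.49)
  x1 <- rnorm(n); x1 <- (x1 - mean(x1)) / sd(x1)
  x2 <- residuals(lm(rnorm(n) ~ x1)); x2 <- x2 / sd(x2)
  x3 <- 0.7 * x1 + sqrt(1 - 0.49) * x2
  v <- vif_values(cbind(a = x1, b = x3))
  expect_equal(unname(v), rep(1 / (1 - 0.49), 2), tolerance = 1e-6)
})

test_that("the collinearity screen drops duplicates and constants but keeps r = 0.7 pairs", {
  n <- 120
  set.seed(5)
  x1 <- rnorm(n); x1 <- (x1 - mean(x1)) / sd(x1)
  o <- residuals(lm(rnorm(n) ~ x1)); o <- o / sd(o)
  x3 <- 0.7 * x1 + sqrt(1 - 0.49) * o
  tab <- data.frame(label = rbinom(n, 1, 0.5),
                    a = x1, b = x3, dup = x1, flat = 1)
  expect_warning(out <- vif_screen(tab, threshold = 3, corr_cut = 0.7),
                 "constant")
  kept <- setdiff(colnames(out), "label")
  expect_false("flat" %in% kept)
  expect_length(intersect(c("a", "dup"), kept), 1)  # one of the twins goes
  expect_true("b" %in% kept)                        # r = 0.7 is allowed
  expect_true(all(attr(out, "vif") <= 3))
  # two centred orthogonal columns: both retained at VIF 1
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 2), n, 2))))[, 2:3]
  out2 <- vif_screen(data.frame(label = rbinom(n, 1, 0.5),
                                u = Q[, 1], v = Q[, 2]))
  expect_setequal(setdiff(colnames(out2), "label"), c("u", "v"))
  expect_equal(unname(attr(out2, "vif")), c(1, 1), tolerance = 1e-9)
})

test_that("AUC equals the Mann-Whitney statistic and is rank-invariant", {
  expect_equal(evaluate_auc(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_equal(evaluate_auc(c(5, 6, 1, 2), c(1, 1, 0, 0)), 1)
  expect_equal(evaluate_auc(rep(0.3, 10), rep(c(1, 0), 5)), 0.5)
  set.seed(6)
  s <- runif(50); lab <- rbinom(50, 1, 0.5)
  a <- evaluate_auc(s, lab)
  # invariance under strictly monotone transforms
  expect_equal(evaluate_auc(qlogis(s), lab), a)
  expect_equal(evaluate_auc(s^3 + 2, lab), a)
  # agreement with the independent ROC implementation
  expect_equal(a, as.numeric(pROC::auc(pROC::roc(lab, s, quiet = TRUE,
                                                 direction = "<"))))
  expect_error(evaluate_auc(s, rep(1, 50)), "both classes")
})

test_that("TSS maximization agrees with a brute-force threshold scan", {
  out <- evaluate_tss(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))
  expect_equal(out$tss, 0.5)
  expect_equal(out$threshold, 0.25)  # smallest maximizer
  expect_equal(evaluate_tss(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$tss, 1)
  expect_equal(evaluate_tss(rep(0.5, 8), rep(c(1, 0), 4))$tss, 0)
  for (seed in 1:5) {
    set.seed(seed)
    s <- round(runif(40), 2)
    lab <- rbinom(40, 1, 0.5)
    if (length(unique(lab)) < 2) next
    got <- evaluate_tss(s, lab)
    # brute force: every threshold between -inf and +inf matters only at
    # score values; evaluate on a fine grid around each score
    grid <- sort(unique(c(s - 1e-6, s + 1e-6, 0, 1)))
    bf <- max(vapply(grid, function(t)
      sum(lab == 1 & s >= t) / sum(lab == 1) +
        sum(lab == 0 & s < t) / sum(lab == 0) - 1, 0))
    expect_equal(got$tss, bf, tolerance = 1e-9)
  }
})

test_that("learners fit separable data, stay at chance on shuffled labels, and are seed-deterministic", {
  set.seed(7)
  n <- 120
  x <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("u_1km", "v_1km")))
  y <- as.integer(x[, 1] > median(x[, 1]))
  tab <- data.frame(label = y, x, check.names = FALSE)
  attr(tab, "scales_m") <- 1000
  for (lrn in list(learner_spec("rf", num_trees = 200),
                   learner_spec("logistic"))) {
    m <- fit_suitability(tab, lrn, seed = 1)
    p <- predict_suitability(m, x)
    expect_gte(evaluate_auc(p, y), 0.95)
    m2 <- fit_suitability(tab, lrn, seed = 1)
    expect_identical(predict_suitability(m2, x), p)
  }
  # null labels: cross-validated AUC hovers around 0.5
  aucs <- vapply(1:10, function(s) {
    set.seed(s)
    tabs <- tab
    tabs$label <- sample(tabs$label)
    evaluate_model(tabs, learner_spec("logistic"), k = 5, seed = s)$auc
  }, 0)
  expect_true(all(aucs > 0.3 & aucs < 0.7))
  expect_gt(mean(aucs > 0.4 & aucs < 0.6), 0.5)
  expect_error(fit_suitability(tab[1:2, ], learner_spec("logistic")),
               "degenerate")
})

test_that("scale selection follows max AUC, then max TSS, then smallest scale", {
  ev <- data.frame(scale_m = c(1, 2, 4, 8, 16, 32) * 1000,
                   auc = c(0.923, 0.935, 0.940, 0.934, 0.954, 0.948),
                   tss = c(0.836, 0.832, 0.802, 0.727, 0.849, 0.794))
  expect_equal(select_scale(ev), 16000)
  ev2 <- data.frame(scale_m = c(1, 8, 32) * 1000, auc = c(0.9, 0.9, 0.9),
                    tss = c(0.5, 0.8, 0.6))
  expect_equal(select_scale(ev2), 8000)
  ev3 <- data.frame(scale_m = 4000, auc = 0.7, tss = 0.4)
  expect_equal(select_scale(ev3), 4000)
  # full tie: smallest scale
  ev4 <- data.frame(scale_m = c(8, 2) * 1000, auc = 0.9, tss = 0.5)
  expect_equal(select_scale(ev4), 2000)
  expect_error(select_scale(ev[0, ]), "at least one")
})

test_that("surface prediction is consistent with row prediction and tracks a monotone learner", {
  g <- grid_spec(30, 30, 1000)
  cov <- generate_covariate_field(g, 3000, 12)
  covs <- list(grad = cov)
  truth <- generate_true_suitability(covs, 4, 2000)
  pres <- sample_occurrences(truth, 60, seed = 1)
  abs <- sample_pseudo_absences(g, pres, 0, 120, seed = 2)
  pts <- occurrence_set(rbind(as.data.frame(pres),
                              transform(as.data.frame(abs), id = id + 60)))
  tab <- build_feature_table(pts, covs, 2000)
  m <- fit_suitability(tab, learner_spec("logistic"), seed = 3)
  surf <- predict_surface(m, covs)
  expect_true(all(surf$values >= 0 & surf$values <= 1))
  # prediction at a training point's cell equals its row prediction
  row_pred <- predict_suitability(m, tab[, -1, drop = FALSE])
  cell_pred <- extract_values(surf, pts$x, pts$y)
  expect_equal(unname(cell_pred), unname(row_pred), tolerance = 1e-9)
  # monotone single-covariate learner: surface ordering follows the
  # focal covariate ordering
  feat <- focal_mean(cov, 2000)
  expect_gt(cor(as.vector(surf$values), as.vector(feat$values),
                method = "spearman"), 0.99)
})
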