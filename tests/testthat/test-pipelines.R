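# The nine classification protocols: normalization, reducers, SKFCV.

test_that("z-score normalization fits on train and transfers its statistics", {
  tr <- matrix(c(0, 2), ncol = 1)
  zs <- zscore_fit(tr)
  expect_equal(as.numeric(zscore_apply(zs, tr)),
               c(-1, 1) / sqrt(2))                 # sample SD = sqrt(2)
  expect_equal(as.numeric(zscore_apply(zs, matrix(1))), 0)

  expect_warning(zs2 <- zscore_fit(cbind(a = c(1, 1, 1), b = c(1, 2, 3))),
                 "constant")
  expect_equal(zscore_apply(zs2, cbind(a = c(5, 7), b = c(2, 2)))[, "a"],
               c(0, 0))

  expect_error(zscore_fit(matrix(1, 1, 2)), "at least 2")

  set.seed(9)
  x <- matrix(rnorm(100), 20, 5)
  z <- zscore_apply(zs3 <- zscore_fit(x), x)
  expect_lt(max(abs(colMeans(z))), 1e-12)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-12)
  # idempotence: re-normalizing an already normalized train matrix
  expect_lt(max(abs(zscore_apply(zscore_fit(z), z) - z)), 1e-10)
})

test_that("the nine protocol ids map to their base model and reducer", {
  pairs <- list(C1 = c("lr", "none"), C2 = c("lr", "rfe"),
                C3 = c("lr", "pca"), C4 = c("lr", "roc_fr"),
                C5 = c("svm", "none"), C6 = c("svm", "rfe"),
                C7 = c("svm", "pca"), C8 = c("svm", "roc_fr"),
                C9 = c("lasso", "none"))
  for (id in names(pairs)) {
    sp <- classifier_spec(id)
    expect_equal(c(sp$base, sp$reducer), pairs[[id]])
  }
  expect_length(classifier_spec("C1")$hyper_grid, 7)
  expect_length(classifier_spec("C9")$hyper_grid, 9)
  expect_error(classifier_spec("C10"), "unknown")
})

test_that("reducers select or project as specified", {
  # ROCfr keeps the informative feature and drops most nulls
  hits <- 0; nulls_kept <- 0
  for (s in 1:20) {
    co <- simulate_cohort(simulation_spec(60, 60, 10,
                                          effect_sizes = c(2, rep(0, 9)),
                                          seed = s))
    zs <- zscore_fit(co$features)
    x <- zscore_apply(zs, co$features)
    tr <- reduce_features(classifier_spec("C4", roc_fr_threshold = 0.2),
                          x, co$labels)
    hits <- hits + (1 %in% tr$keep)
    nulls_kept <- nulls_kept + length(setdiff(tr$keep, 1))
  }
  expect_equal(hits, 20)
  expect_lt(nulls_kept / 20, 5)       # most of the 9 nulls excluded

  # ROCfr fallback: impossible threshold keeps the single best feature
  co <- separable_cohort(15, 15, seed = 2)
  tr <- reduce_features(classifier_spec("C4", roc_fr_threshold = 1.5),
                        co$features, co$labels)
  expect_length(tr$keep, 1)
  expect_true(tr$flagged)

  # PCA on rank-2 data keeps at most 2 components
  set.seed(10)
  b <- matrix(rnorm(40), 20, 2)
  x <- b %*% matrix(rnorm(10), 2, 5)  # rank 2, 5 columns
  tr <- reduce_features(classifier_spec("C3"), scale(x), rep(0:1, 10))
  expect_lte(ncol(tr$rotation), 2)
  expect_equal(dim(apply_reducer(tr, scale(x))),
               c(20L, ncol(tr$rotation)))

  # RFE down to one feature retains the only separating feature
  co <- separable_cohort(30, 30, seed = 3)
  x <- zscore_apply(zscore_fit(co$features), co$features)
  for (base in c("C2", "C6")) {
    tr <- reduce_features(classifier_spec(base), x, co$labels, n_keep = 1)
    expect_equal(tr$keep, 1L)
  }
})

test_that("class weighting recovers the minority class on imbalanced data", {
  # 9:1 imbalanced but separable: the weighted linear model must find it
  co <- simulate_cohort(simulation_spec(10, 90, 2, effect_sizes = c(6, 0),
                                        seed = 12))
  x <- zscore_apply(zscore_fit(co$features), co$features)
  for (base in c("lr", "svm")) {
    m <- downstrap:::train_model(base, x, co$labels, 1)
    pr <- downstrap:::predict_model(m, x)
    expect_equal(downstrap:::yi_from_classes(pr$class, co$labels), 1)
  }
})

test_that("SKFCV attains perfect scores on a separable cohort", {
  co <- separable_cohort(30, 30, seed = 21)
  st <- setup("sep", 20, 20, 10, 10, k_folds = 4)
  for (id in c("C1", "C5", "C9")) {
    r <- run_skfcv(co, st, classifier_spec(id), 1, base_seed = 5)
    expect_equal(r$yi_vs, 1)
    expect_equal(r$yi_tes, 1)
    expect_equal(r$auc_tes, 1)
  }
})

test_that("cross-validation aggregation arithmetic is exact", {
  co <- simulate_cohort(simulation_spec(40, 40, 3, effect_sizes = c(1, 0.5, 0),
                                        seed = 14))
  st <- setup("agg", 25, 25, 10, 10, k_folds = 5)
  r <- run_skfcv(co, st, classifier_spec("C1"), 1, base_seed = 6)
  expect_equal(r$yi_vs, mean(r$fold_yis))
  expect_equal(r$sd_vs, sd(r$fold_yis))
  expect_equal(r$selected_fold, which.max(r$fold_yis))
  expect_true(r$yi_tes >= -1 && r$yi_tes <= 1)
  expect_true(r$auc_tes >= 0 && r$auc_tes <= 1)
})

test_that("identical inputs and seed give identical results; TES never leaks", {
  co <- simulate_cohort(simulation_spec(50, 50, 4, effect_sizes = 0.5,
                                        seed = 15))
  st <- setup("det", 30, 30, 15, 15, k_folds = 3)
  a <- run_skfcv(co, st, classifier_spec("C3"), 2, base_seed = 8)
  b <- run_skfcv(co, st, classifier_spec("C3"), 2, base_seed = 8)
  expect_identical(a[c("fold_yis", "yi_vs", "yi_tes", "auc_tes")],
                   b[c("fold_yis", "yi_vs", "yi_tes", "auc_tes")])

  # leakage check: changing the TES labels cannot change the fitted models
  tr_i <- c(1:30, 51:80)               # both classes in train and in TES
  x <- co$features[tr_i, ]; y <- co$labels[tr_i]
  xt <- co$features[-tr_i, ]; yt <- co$labels[-tr_i]
  r1 <- downstrap:::skfcv_matrix(x, y, 3, classifier_spec("C1"), seed = 4,
                                 x_tes = xt, y_tes = yt)
  r2 <- downstrap:::skfcv_matrix(x, y, 3, classifier_spec("C1"), seed = 4,
                                 x_tes = xt, y_tes = 1L - yt)
  expect_identical(r1$fold_yis, r2$fold_yis)
  expect_identical(r1$selected_hyper, r2$selected_hyper)
  expect_equal(r1$yi_tes, -r2$yi_tes)   # flipped labels flip the Youden index
})

test_that("aggregates over runs and the coverage fraction are consistent", {
  co <- simulate_cohort(simulation_spec(60, 60, 3, effect_sizes = c(1.2, 0.6, 0),
                                        seed = 16))
  st <- setup("runs", 30, 30, 20, 20, k_folds = 3)
  agg <- run_ml_setup(co, st, classifier_spec("C1"), n_runs = 4,
                      base_seed = 9)
  yi_vs <- vapply(agg$runs, `[[`, numeric(1), "yi_vs")
  expect_equal(agg$mean_vs, mean(yi_vs))
  expect_equal(agg$mean_abs_diff,
               mean(abs(yi_vs - vapply(agg$runs, `[[`, numeric(1),
                                       "yi_tes"))))
  cov <- coverage_fraction(agg$runs)
  expect_true(cov >= 0 && cov <= 100)

  # hand-built coverage cases
  mk <- function(vs, sd, tes) list(yi_vs = vs, sd_vs = sd, yi_tes = tes)
  expect_equal(coverage_fraction(list(mk(0.6, 0.1, 0.65),
                                      mk(0.6, 0.1, 0.75))), 50)
  expect_equal(coverage_fraction(list(mk(0.5, 0, 0.5))), 100)
})

test_that("mean validation performance grows with the set-up size", {
  # many weak, partly correlated features: the regime where a linear model
  # keeps improving as cases are added instead of saturating immediately
  co <- simulate_cohort(simulation_spec(
    250, 250, 30, effect_sizes = 0.25,
    correlation = list(list(features = 1:10, rho = 0.3)), seed = 17))
  sizes <- c(20, 80, 200)
  means <- vapply(sizes, function(n) {
    st <- setup(paste0("g", n), n, n, 0, 0, k_folds = min(5L, n %/% 10L))
    run_ml_setup(co, st, classifier_spec("C1"), n_runs = 10,
                 base_seed = 10, keep_runs = FALSE)$mean_vs
  }, numeric(1))
  expect_gt(means[3], means[1])
})
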