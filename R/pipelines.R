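# The nine multivariate classification protocols: logistic regression,
# linear SVM and LASSO, alone or behind RFE / PCA / univariate-ROC feature
# reduction, tuned by stratified K-fold cross-validation with per-fold
# z-score normalization and inverse-frequency class weighting.

#' Specification of a classification protocol
#'
#' The nine protocols pair a linear base model with an optional
#' dimensionality reducer:
#' C1 = LR, C2 = RFE-LR, C3 = PCA-LR, C4 = ROCfr-LR, C5 = SVM,
#' C6 = RFE-SVM, C7 = PCA-SVM, C8 = ROCfr-SVM, C9 = LASSO.
#' LR is an L2-regularized logistic regression (tuned over the inverse
#' regularization strength), SVM a linear-kernel support vector machine
#' (tuned over the penalty parameter) and LASSO an L1-regularized linear
#' model on 0/1 targets (tuned over the L1 constant) whose continuous output
#' is thresholded at 0.5 for classification.
#'
#' @param id one of `"C1"`..`"C9"`.
#' @param hyper_grid candidate regularization values; defaults to
#'   `10^(-3..3)` (7 points) for LR and SVM and `10^(-4..0)` (9 points) for
#'   the LASSO L1 constant.
#' @param roc_fr_threshold training-Youden threshold for the ROCfr reducer
#'   (only used by C4/C8). 0.20 suits a permissive radiomics screen; 0.75
#'   suits a cohort where almost every feature clears 0.20.
#' @param rfe_fracs fractions of features the RFE reducer may retain; tuned
#'   within the fold grid search.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(id, hyper_grid = NULL, roc_fr_threshold = 0.2,
                            rfe_fracs = c(0.25, 0.5, 0.75)) {
  defs <- list(
    C1 = c("lr", "none"), C2 = c("lr", "rfe"), C3 = c("lr", "pca"),
    C4 = c("lr", "roc_fr"), C5 = c("svm", "none"), C6 = c("svm", "rfe"),
    C7 = c("svm", "pca"), C8 = c("svm", "roc_fr"), C9 = c("lasso", "none"))
  if (!id %in% names(defs)) stop("unknown classifier id: ", id)
  base <- defs[[id]][1]
  reducer <- defs[[id]][2]
  hyper_grid <- hyper_grid %||%
    if (base == "lasso") 10^seq(-4, 0, by = 0.5) else 10^seq(-3, 3)
  structure(
    list(id = id, base = base, reducer = reducer, hyper_grid = hyper_grid,
         roc_fr_threshold = roc_fr_threshold, rfe_fracs = rfe_fracs),
    class = "classifier_spec"
  )
}

#' Fit z-score normalization statistics on training data
#'
#' Mean and sample standard deviation per feature, learned on the training
#' part only; validation and test data must be transformed with these same
#' statistics ([zscore_apply()]). Zero-variance columns are mapped to 0 with
#' a warning.
#'
#' @param train numeric matrix with >= 2 rows.
#' @return list with `mean`, `sd` (class `zscore_stats`).
#' @export
zscore_fit <- function(train) {
  if (nrow(train) < 2L) stop("z-score fit needs at least 2 training rows")
  m <- colMeans(train)
  s <- apply(train, 2, stats::sd)
  if (any(s == 0)) {
    warning("constant feature column(s) mapped to 0 by z-score: ",
            paste(which(s == 0), collapse = ", "))
  }
  structure(list(mean = m, sd = s), class = "zscore_stats")
}

#' Apply fitted z-score statistics to a matrix
#' @param stats a `zscore_stats` object from [zscore_fit()].
#' @param x numeric matrix with the same columns as the training data.
#' @return normalized matrix; zero-variance columns become 0.
#' @export
zscore_apply <- function(stats, x) {
  s <- ifelse(stats$sd == 0, 1, stats$sd)
  out <- sweep(sweep(x, 2, stats$mean), 2, s, "/")
  if (any(stats$sd == 0)) out[, stats$sd == 0] <- 0
  out
}

# ---- base models ------------------------------------------------------

balanced_weights <- function(y) {
  n <- length(y)
  w1 <- n / (2 * sum(y == 1L))
  w0 <- n / (2 * sum(y == 0L))
  ifelse(y == 1L, w1, w0)
}

# glmnet needs >= 2 predictor columns; pad single-column inputs with a zero
# dummy column (its coefficient is irrelevant).
pad2 <- function(x) if (ncol(x) >= 2L) x else cbind(x, .pad = 0)

# Fit one base model at a single hyperparameter value.
train_model <- function(base, x, y, hyper) {
  w <- balanced_weights(y)
  model <- switch(base,
    lr = {
      lam <- 1 / (nrow(x) * hyper)   # hyper = inverse regularization strength
      # glmnet warns on very small classes; tiny folds are routine here
      fit <- suppressWarnings(
        glmnet::glmnet(pad2(x), y, family = "binomial", alpha = 0,
                       lambda = lam, weights = w, standardize = FALSE))
      list(fit = fit, s = lam)
    },
    svm = {
      yf <- factor(y, levels = c(0L, 1L))
      cw <- c("0" = unique(w[y == 0L]), "1" = unique(w[y == 1L]))
      fit <- e1071::svm(x, yf, kernel = "linear", cost = hyper, scale = FALSE,
                        class.weights = cw)
      list(fit = fit)
    },
    lasso = {
      fit <- suppressWarnings(
        glmnet::glmnet(pad2(x), as.numeric(y), family = "gaussian",
                       alpha = 1, lambda = hyper, weights = w,
                       standardize = FALSE))
      list(fit = fit, s = hyper)
    },
    stop("unknown base model: ", base))
  structure(c(model, list(base = base, hyper = hyper, p = ncol(x))),
            class = "base_model")
}

# Predict class (0/1) and continuous score (higher = more positive).
predict_model <- function(model, x) {
  switch(model$base,
    lr = {
      eta <- as.numeric(glmnet::predict.glmnet(
        model$fit, pad2(x), s = model$s, type = "link"))
      list(class = as.integer(eta >= 0), score = eta)
    },
    svm = {
      pr <- stats::predict(model$fit, x, decision.values = TRUE)
      dec <- attr(pr, "decision.values")
      score <- if (colnames(dec)[1] == "1/0") dec[, 1] else -dec[, 1]
      list(class = as.integer(as.character(pr) == "1"),
           score = as.numeric(score))
    },
    lasso = {
      yhat <- as.numeric(glmnet::predict.glmnet(
        model$fit, pad2(x), s = model$s))
      list(class = as.integer(yhat >= 0.5), score = yhat)
    })
}

# Linear coefficient magnitudes used by RFE to rank features.
coef_magnitude <- function(base, x, y) {
  if (base == "svm") {
    m <- train_model("svm", x, y, 1)
    w <- t(m$fit$coefs) %*% m$fit$SV
    abs(as.numeric(w))[seq_len(ncol(x))]
  } else {
    m <- train_model(base, x, y, if (base == "lasso") 0.01 else 1)
    cf <- as.numeric(glmnet::coef.glmnet(m$fit, s = m$s))[-1]
    abs(cf)[seq_len(ncol(x))]
  }
}

# ---- reducers ---------------------------------------------------------

#' Fit a dimensionality reducer on (normalized) training data
#'
#' `rfe` ranks features by recursive elimination of the smallest-magnitude
#' coefficient of the linear base model and keeps the top `n_keep`; `pca`
#' fits an orthogonal projection on the training data only, retaining the
#' smallest number of components explaining >= 95% of the variance (capped
#' at `nrow - 1`); `roc_fr` keeps the features whose training Youden index
#' exceeds the spec's threshold, falling back to the single best feature
#' (flagged) when none qualifies.
#'
#' @param spec a [classifier_spec()].
#' @param train_features normalized training matrix.
#' @param train_labels binary 0/1 labels.
#' @param n_keep for `rfe`: number of features to retain.
#' @return A transformer object (class `reducer`) reapplicable with
#'   [apply_reducer()]; has fields `type`, and `keep` (indices) or
#'   `rotation`.
#' @export
reduce_features <- function(spec, train_features, train_labels,
                            n_keep = NULL) {
  type <- spec$reducer
  tr <- switch(type,
    none = list(type = "none"),
    rfe = {
      n_keep <- n_keep %||% max(1L, round(0.5 * ncol(train_features)))
      rank <- rfe_ranking(spec$base, train_features, train_labels,
                          min_keep = 1L)
      list(type = "rfe", keep = sort(rank[seq_len(n_keep)]))
    },
    pca = {
      pc <- stats::prcomp(train_features, center = FALSE, scale. = FALSE)
      v <- pc$sdev^2
      k <- which(cumsum(v) / sum(v) >= 0.95)[1]
      k <- min(k, nrow(train_features) - 1L, ncol(train_features))
      k <- max(k, 1L)
      list(type = "pca", rotation = pc$rotation[, seq_len(k), drop = FALSE])
    },
    roc_fr = {
      yis <- apply(train_features, 2, function(v)
        youden_optimal_cutoff(v, train_labels)$yi)
      keep <- which(yis > spec$roc_fr_threshold)
      flagged <- length(keep) == 0L
      if (flagged) keep <- which.max(yis)
      list(type = "roc_fr", keep = keep, flagged = flagged)
    },
    stop("unknown reducer: ", type))
  structure(tr, class = "reducer")
}

# Full RFE ranking: eliminate the weakest feature one at a time down to
# `min_keep`; returns feature indices from most to least important, so the
# top-k prefix is the RFE subset of size k for every k at once.
rfe_ranking <- function(base, x, y, min_keep = 1L) {
  active <- seq_len(ncol(x))
  eliminated <- integer(0)
  while (length(active) > min_keep) {
    mag <- coef_magnitude(base, x[, active, drop = FALSE], y)
    drop_i <- which.min(mag)
    eliminated <- c(active[drop_i], eliminated)
    active <- active[-drop_i]
  }
  c(active, eliminated)
}

#' Apply a fitted reducer to a new (normalized) matrix
#' @param transformer a `reducer` from [reduce_features()].
#' @param x normalized matrix.
#' @return reduced matrix.
#' @export
apply_reducer <- function(transformer, x) {
  switch(transformer$type,
    none = x,
    rfe = ,
    roc_fr = x[, transformer$keep, drop = FALSE],
    pca = x %*% transformer$rotation)
}

# ---- grid search ------------------------------------------------------

yi_from_classes <- function(pred, y) {
  se <- mean(pred[y == 1L] == 1L)
  sp <- mean(pred[y == 0L] == 0L)
  se + sp - 1
}

# Reducer settings tuned jointly with the hyperparameter grid: RFE retained
# counts form a grid, the other reducers have a single setting (fitted per
# fold-train regardless).
reducer_settings <- function(spec, xtr, ytr) {
  if (spec$reducer == "rfe") {
    rank <- rfe_ranking(spec$base, xtr, ytr, min_keep = 1L)
    lapply(spec$rfe_fracs, function(f) {
      k <- max(1L, round(f * ncol(xtr)))
      structure(list(type = "rfe", keep = sort(rank[seq_len(k)])),
                class = "reducer")
    })
  } else {
    list(reduce_features(spec, xtr, ytr))
  }
}

# Evaluate every (reducer setting, hyperparameter) candidate on one fold:
# fit on the fold-train, score each candidate on the fold-VS. Returns the
# per-candidate YI and AUC vectors (candidates ordered as setting-major,
# hyperparameter-minor).
eval_fold_candidates <- function(spec, xtr, ytr, xvs, yvs) {
  yis <- aucs <- numeric(0)
  settings <- reducer_settings(spec, xtr, ytr)
  for (tr in settings) {
    xtr_r <- apply_reducer(tr, xtr)
    xvs_r <- apply_reducer(tr, xvs)
    for (h in spec$hyper_grid) {
      model <- train_model(spec$base, xtr_r, ytr, h)
      pr <- predict_model(model, xvs_r)
      yis <- c(yis, yi_from_classes(pr$class, yvs))
      aucs <- c(aucs, auc(pr$score, yvs))
    }
  }
  list(yi = yis, auc = aucs, n_settings = length(settings))
}

# Candidate index -> (reducer setting index, hyperparameter value).
candidate_at <- function(spec, n_settings, cand) {
  nh <- length(spec$hyper_grid)
  list(setting = (cand - 1L) %/% nh + 1L,
       hyper = spec$hyper_grid[[(cand - 1L) %% nh + 1L]])
}

# ---- SKFCV ------------------------------------------------------------

# Stratified fold assignment: within each class, a seeded shuffle dealt
# round-robin into K folds.
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Cross-validation core on an explicit matrix: used both by the set-up
# protocol (run_skfcv) and by the downsampling curves. Tuning is joint
# across folds: every (reducer setting, hyperparameter) candidate is scored
# on all K validation folds, the candidate with the best fold-mean score is
# chosen, and the K fold models at that setting define the per-fold
# performances Y^VS-K. The single fold model with the best validation score
# is then frozen (normalization statistics, transformer, weights) and
# applied to TES.
skfcv_matrix <- function(x, y, k, spec, seed, score = "youden",
                         x_tes = NULL, y_tes = NULL) {
  if (min(sum(y == 1L), sum(y == 0L)) < k) {
    stop("a fold would contain a single class; use a smaller K")
  }
  fold <- stratified_folds(y, k, seed)
  yi_mat <- auc_mat <- NULL           # folds x candidates
  n_settings <- 1L
  for (f in seq_len(k)) {
    tr_i <- fold != f
    zs <- zscore_fit(x[tr_i, , drop = FALSE])
    xtr <- zscore_apply(zs, x[tr_i, , drop = FALSE])
    xvs <- zscore_apply(zs, x[!tr_i, , drop = FALSE])
    ev <- eval_fold_candidates(spec, xtr, y[tr_i], xvs, y[!tr_i])
    if (is.null(yi_mat)) {
      yi_mat <- matrix(NA_real_, k, length(ev$yi))
      auc_mat <- matrix(NA_real_, k, length(ev$yi))
      n_settings <- ev$n_settings
    }
    yi_mat[f, ] <- ev$yi
    auc_mat[f, ] <- ev$auc
  }
  crit_mat <- if (score == "youden") yi_mat else auc_mat
  cand <- which.max(colMeans(crit_mat))
  fold_yis <- yi_mat[, cand]
  fold_aucs <- auc_mat[, cand]
  sel <- which.max(crit_mat[, cand])
  chosen <- candidate_at(spec, n_settings, cand)

  yi_tes <- auc_tes <- NA_real_
  if (!is.null(x_tes) && length(y_tes) > 0) {
    # rebuild the selected fold model deterministically and freeze it
    tr_i <- fold != sel
    zs <- zscore_fit(x[tr_i, , drop = FALSE])
    xtr <- zscore_apply(zs, x[tr_i, , drop = FALSE])
    transformer <- reducer_settings(spec, xtr, y[tr_i])[[chosen$setting]]
    model <- train_model(spec$base, apply_reducer(transformer, xtr),
                         y[tr_i], chosen$hyper)
    xt <- apply_reducer(transformer, zscore_apply(zs, x_tes))
    pr <- predict_model(model, xt)
    yi_tes <- yi_from_classes(pr$class, y_tes)
    auc_tes <- auc(pr$score, y_tes)
  }
  structure(
    list(fold_yis = fold_yis, fold_aucs = fold_aucs,
         yi_vs = mean(fold_yis), sd_vs = sd_or_zero(fold_yis),
         auc_vs = mean(fold_aucs), sd_auc_vs = sd_or_zero(fold_aucs),
         yi_tes = yi_tes, auc_tes = auc_tes,
         selected_fold = sel,
         selected_hyper = chosen$hyper,
         selected_setting = chosen$setting),
    class = "cv_run_result"
  )
}

#' One run of the stratified K-fold classification protocol
#'
#' Draws the run's random split, then runs the SKFCV protocol on TRS+VS: per
#' fold, features are z-scored with the fold-train statistics and the
#' reducer is fitted on the fold-train; the regularization grid (plus the
#' RFE retained-count grid where applicable) is tuned jointly across folds
#' by the fold-mean validation score, the K fold models at the chosen
#' setting give the per-fold performances, and the fold model with the
#' highest validation score -- frozen normalization, transformer,
#' hyperparameters and weights -- is applied to TES. Class imbalance is
#' handled throughout by weighting each class inversely to its frequency.
#'
#' @param cohort a [cohort()].
#' @param setup a [setup()].
#' @param spec a [classifier_spec()].
#' @param run_index run number (1-based).
#' @param base_seed integer base seed.
#' @param score fold-selection figure of merit: `"youden"` (default) or
#'   `"auc"`.
#' @return A `cv_run_result`: `fold_yis`, `fold_aucs`, `yi_vs` (mean of fold
#'   YIs), `sd_vs` (their sample SD), `auc_vs`, `yi_tes`, `auc_tes`,
#'   `selected_fold`, `selected_hyper`.
#' @export
run_skfcv <- function(cohort, setup, spec, run_index, base_seed,
                      score = "youden") {
  plan <- draw_split(cohort, setup, run_index, base_seed)
  x <- cohort$features[plan$trvs_indices, , drop = FALSE]
  y <- cohort$labels[plan$trvs_indices]
  has_tes <- length(plan$tes_indices) > 0
  res <- skfcv_matrix(
    x, y, setup$k_folds, spec,
    seed = derive_seed(base_seed, "folds", spec$id, setup$id, run_index),
    score = score,
    x_tes = if (has_tes) cohort$features[plan$tes_indices, , drop = FALSE],
    y_tes = if (has_tes) cohort$labels[plan$tes_indices])
  res$run_index <- as.integer(run_index)
  res
}

#' Repeated-run classification protocol for one set-up
#'
#' Runs [run_skfcv()] for `n_runs` independent random splits and aggregates:
#' mean and sample SD of the per-run validation Youden index and AUC, of the
#' TES metrics, and the mean signed and absolute difference between each
#' run's validation and test Youden index.
#'
#' @inheritParams run_skfcv
#' @param n_runs number of repeated splits (default 50).
#' @param keep_runs keep the per-run `cv_run_result` list (needed by
#'   [coverage_fraction()]); default TRUE.
#' @return list of class `ml_aggregate` with `mean_vs`, `sd_vs`, `mean_tes`,
#'   `sd_tes`, `mean_auc_vs`, `sd_auc_vs`, `mean_auc_tes`, `sd_auc_tes`,
#'   `mean_diff`, `mean_abs_diff`, `n_runs`, and `runs` (when kept).
#' @export
run_ml_setup <- function(cohort, setup, spec, n_runs = 50L, base_seed = 1L,
                         score = "youden", keep_runs = TRUE) {
  runs <- lapply(seq_len(n_runs), function(i)
    run_skfcv(cohort, setup, spec, i, base_seed, score))
  yi_vs <- vapply(runs, `[[`, numeric(1), "yi_vs")
  yi_tes <- vapply(runs, `[[`, numeric(1), "yi_tes")
  auc_vs <- vapply(runs, `[[`, numeric(1), "auc_vs")
  auc_tes <- vapply(runs, `[[`, numeric(1), "auc_tes")
  out <- list(
    classifier = spec$id, setup = setup$id,
    mean_vs = mean(yi_vs), sd_vs = sd_or_zero(yi_vs),
    mean_tes = mean(yi_tes), sd_tes = sd_or_zero(yi_tes),
    mean_auc_vs = mean(auc_vs), sd_auc_vs = sd_or_zero(auc_vs),
    mean_auc_tes = mean(auc_tes), sd_auc_tes = sd_or_zero(auc_tes),
    mean_diff = mean(yi_vs - yi_tes),
    mean_abs_diff = mean(abs(yi_vs - yi_tes)),
    n_runs = as.integer(n_runs),
    low_precision = n_runs < 10L)
  if (keep_runs) out$runs <- runs
  structure(out, class = "ml_aggregate")
}

#' Reference logistic-regression cross-validation performance
#'
#' The canonical "logistic regression with 10-fold cross-validation"
#' analysis used as a published reference for the WDBC cohort: a plain
#' maximum-likelihood logistic regression (no regularization, no class
#' weighting) fitted on each training part of a stratified K-fold split and
#' scored on the held-out fold. Consistent with how every cross-validated
#' figure of merit is reported here, the Youden index is computed per fold
#' (at the optimal cutoff of the fold's out-of-fold probabilities -- the
#' same maximizing-cutoff YI convention the univariate analysis uses) and
#' averaged over the K folds, then over independent fold shuffles. Logistic
#' regression is affine-equivariant, so no feature normalization is needed.
#'
#' @param cohort a [cohort()].
#' @param k number of folds (default 10).
#' @param n_repeats independent fold shuffles (default 20).
#' @param base_seed integer base seed.
#' @return list with `mean_yi`, `sd_yi`, `yis` (per-repeat values).
#' @export
reference_lr_cv <- function(cohort, k = 10L, n_repeats = 20L,
                            base_seed = 1L) {
  x <- cohort$features
  y <- cohort$labels
  yis <- vapply(seq_len(n_repeats), function(r) {
    fold <- stratified_folds(y, k, derive_seed(base_seed, "lr_cv", r))
    fold_yi <- vapply(seq_len(k), function(f) {
      tr <- fold != f
      fit <- suppressWarnings(
        stats::glm(y ~ ., family = stats::binomial(),
                   data = data.frame(y = y[tr], x[tr, , drop = FALSE])))
      prob <- suppressWarnings(
        stats::predict(fit, data.frame(x[!tr, , drop = FALSE]),
                       type = "response"))
      youden_optimal_cutoff(prob, y[!tr], directions = "greater")$yi
    }, numeric(1))
    mean(fold_yi)
  }, numeric(1))
  list(mean_yi = mean(yis), sd_yi = sd_or_zero(yis), yis = yis)
}

#' Coverage of the test performance by the cross-validation band
#'
#' Percentage of runs for which the test Youden index falls inside the
#' cross-validation band `yi_vs +/- sd_vs` -- a measure of how reliable the
#' cross-validated estimate is as a predictor of independent-test
#' performance.
#'
#' @param results list of `cv_run_result` objects (e.g. the `runs` field of
#'   [run_ml_setup()]'s output, possibly pooled over classifiers).
#' @return percentage in \eqn{[0, 100]}.
#' @export
coverage_fraction <- function(results) {
  stopifnot(length(results) >= 1L)
  inside <- vapply(results, function(r)
    abs(r$yi_tes - r$yi_vs) <= r$sd_vs, logical(1))
  100 * mean(inside)
}
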