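# The downsampling strategy: performance curves over nested subsample sizes,
# SD-decay and logarithmic performance-growth fits, the convergence sample
# size N_c, and the extrapolated performance at convergence (Yec).
#
# Natural logarithms are used throughout; both N_c and Yec are invariant
# under the choice of logarithm base (the coefficients rescale).

#' Build a downsampling performance curve
#'
#' From the N available cases, generates P subsample sizes
#' `N_p = N - (p - 1) S` down to `min_size` (at least 3 sizes are required
#' for the subsequent fits). At each size, `n_runs` independent stratified
#' subsamples are drawn (class ratio of the N cases preserved,
#' nearest-integer rounding, at least one sample -- two for the multivariate
#' analysis -- per class), the figure of merit is computed on each, and the
#' per-size mean and sample SD over runs form the curve. For the univariate
#' analysis the figure of merit is the resubstitution Youden index (or AUC)
#' of the feature on the subsample; for the multivariate analysis it is the
#' cross-validated `yi_vs` (or `auc_vs`) of the classifier protocol on the
#' subsample.
#'
#' Each size should be a genuine random draw from a strictly larger pool:
#' when the largest size equals the cohort size, the univariate
#' resubstitution value at that point is deterministic (zero SD), which
#' anchors the SD-decay line at zero there and collapses the extrapolation
#' onto the naive estimate. Use `max_size` below the cohort size (as
#' [predict_performance()] does by default) to avoid this; the multivariate
#' analysis is less affected because the stratified fold assignment
#' randomizes every size.
#'
#' @param cohort a [cohort()] holding the N available cases.
#' @param analysis `"roc"` (univariate) or a [classifier_spec()] /
#'   classifier id `"C1"`..`"C9"`.
#' @param feature feature name or index (univariate analysis only).
#' @param metric `"youden"` or `"auc"`.
#' @param s downsampling step S in cases.
#' @param n_runs draws per size (default 50).
#' @param base_seed integer base seed.
#' @param min_size smallest allowed subsample size.
#' @param k_folds optional fixed fold count for the multivariate analysis;
#'   default [default_k_folds()] of each subsample's minority count.
#' @param max_size largest subsample size (default: all available cases);
#'   set below the cohort size to emulate "N available out of a larger
#'   pool", every size then being a genuine random draw.
#' @return An object of class `performance_curve`: data.frame with columns
#'   `size`, `mean`, `sd`, plus attributes `metric`, `analysis`, `step`,
#'   `n_runs`.
#' @export
build_downsampling_curve <- function(cohort, analysis = "roc", feature = NULL,
                                     metric = c("youden", "auc"), s = 8L,
                                     n_runs = 50L, base_seed = 1L,
                                     min_size = 20L, k_folds = NULL,
                                     max_size = NULL) {
  metric <- match.arg(metric)
  n <- n_samples(cohort)
  top <- max_size %||% n
  if (top > n) stop("max_size exceeds the available cases")
  sizes <- seq(top, min_size, by = -s)
  if (length(sizes) < 3L) {
    stop("insufficient patients for extrapolation: only ", length(sizes),
         " subsample size(s) of step ", s, " fit between ", min_size,
         " and ", n, " (need at least 3)")
  }
  is_uni <- identical(analysis, "roc")
  if (is_uni) {
    if (is.null(feature)) stop("univariate analysis requires a feature")
    j <- resolve_features(cohort, feature)[[1]]
    analysis_id <- paste0("roc:", cohort$feature_names[[j]])
  } else {
    spec <- if (inherits(analysis, "classifier_spec")) analysis
            else classifier_spec(analysis)
    analysis_id <- spec$id
  }
  min_pc <- if (is_uni) 1L else 2L
  # nested chains: within a run, every size is a prefix of one stratified
  # permutation, so the curve points of a run share cases and the fitted
  # slope is not dominated by independent between-size sampling noise
  vals <- matrix(NA_real_, length(sizes), n_runs)
  for (i in seq_len(n_runs)) {
    run_seed <- derive_seed(base_seed, "curve", analysis_id, i)
    ord <- with_seed(run_seed, list(
      pos = sample(which(cohort$labels == 1L)),
      neg = sample(which(cohort$labels == 0L))))
    for (p in seq_along(sizes)) {
      np <- sizes[[p]]
      n_pos_p <- round(np * cohort$n_pos / n)
      n_pos_p <- max(min_pc, min(np - min_pc, n_pos_p))
      idx <- c(ord$pos[seq_len(n_pos_p)], ord$neg[seq_len(np - n_pos_p)])
      if (is_uni) {
        v <- cohort$features[idx, j]
        y <- cohort$labels[idx]
        cut <- youden_optimal_cutoff(v, y)
        vals[p, i] <- if (metric == "youden") cut$yi
                      else oriented_auc(v, y, cut$direction)
      } else {
        y <- cohort$labels[idx]
        k <- k_folds %||% default_k_folds(min(sum(y == 1L), sum(y == 0L)))
        res <- skfcv_matrix(cohort$features[idx, , drop = FALSE], y, k, spec,
                            seed = derive_seed(run_seed, "folds", np),
                            score = metric)
        vals[p, i] <- if (metric == "youden") res$yi_vs else res$auc_vs
      }
    }
  }
  means <- rowMeans(vals)
  sds <- apply(vals, 1, sd_or_zero)
  curve <- data.frame(size = sizes, mean = means, sd = sds)
  structure(curve, metric = metric, analysis = analysis_id,
            step = as.integer(s), n_runs = as.integer(n_runs),
            class = c("performance_curve", "data.frame"))
}

#' Linear SD-decay fit and convergence sample size
#'
#' Ordinary least squares of the per-size SD on the size:
#' `SD(N_p) = a - b N_p`. The convergence size `N_c` is where the fitted
#' line crosses zero, `N_c = a / b`. When the slope has the wrong sign
#' (`b <= 0`, SD not decaying), the fit is flagged `no_zero_crossing` and
#' `N_c` is capped at `cap_factor` times the largest size. This is the decay
#' model suited to the univariate analysis, whose run-to-run SD shrinks
#' roughly linearly with the number of cases.
#'
#' @param curve a `performance_curve` (or any data.frame with `size`, `sd`).
#' @param cap_factor cap on `N_c` as a multiple of the largest size
#'   (default 10).
#' @return list with `a`, `b`, `n_c`, `flags` (character vector).
#' @export
fit_sd_linear <- function(curve, cap_factor = 10) {
  fit <- stats::lm(sd ~ size, data = curve)
  a <- unname(stats::coef(fit)[1])
  b <- -unname(stats::coef(fit)[2])
  flags <- character(0)
  if (!is.finite(b) || b <= 1e-12) {  # slope ~0: the line never reaches 0
    flags <- "no_zero_crossing"
    n_c <- cap_factor * max(curve$size)
  } else {
    n_c <- a / b
    if (n_c > cap_factor * max(curve$size)) {
      n_c <- cap_factor * max(curve$size)
      flags <- "capped_n_c"
    }
  }
  list(a = a, b = b, n_c = n_c, flags = flags, model = "linear")
}

#' Logarithmic SD-decay fit and convergence sample size
#'
#' Ordinary least squares of the per-size SD on the natural log of the size:
#' `SD(N_p) = a' - b' log(N_p)`, with `N_c = exp(a' / b')` where the fit
#' crosses zero. Flagging and capping as in [fit_sd_linear()]. This is the
#' decay model suited to the multivariate analysis. `N_c` does not depend on
#' the logarithm base.
#'
#' @inheritParams fit_sd_linear
#' @return list with `a`, `b`, `n_c`, `flags`.
#' @export
fit_sd_log <- function(curve, cap_factor = 10) {
  fit <- stats::lm(sd ~ log(size), data = curve)
  a <- unname(stats::coef(fit)[1])
  b <- -unname(stats::coef(fit)[2])
  flags <- character(0)
  cap <- cap_factor * max(curve$size)
  if (!is.finite(b) || b <= 1e-12) {
    flags <- "no_zero_crossing"
    n_c <- cap
  } else {
    n_c <- exp(a / b)
    if (n_c > cap) {
      n_c <- cap
      flags <- "capped_n_c"
    }
  }
  list(a = a, b = b, n_c = n_c, flags = flags, model = "logarithmic")
}

#' Weighted logarithmic fit of the performance curve
#'
#' Least squares of the per-size mean performance on the natural log of the
#' size, `Y(N_p) = c + d log(N_p)`, each point weighted by the inverse of
#' its SD (floored at `sd_floor` so zero-SD points keep a finite weight).
#' The expected slope sign differs by analysis: the univariate
#' resubstitution Youden index decreases with more cases (`d < 0`, the
#' small-sample optimism vanishes) while the cross-validated multivariate
#' performance increases (`d > 0`). A slope contradicting `expected_sign`
#' is flagged `wrong_sign_slope`; the fit is still returned.
#'
#' @param curve a `performance_curve`.
#' @param expected_sign `"negative"` (univariate) or `"positive"`
#'   (multivariate).
#' @param sd_floor weight floor (default 1e-3).
#' @return list with `c`, `d`, `flags`.
#' @export
fit_perf_weighted_log <- function(curve,
                                  expected_sign = c("positive", "negative"),
                                  sd_floor = 1e-3) {
  expected_sign <- match.arg(expected_sign)
  w <- 1 / pmax(curve$sd, sd_floor)
  fit <- stats::lm(mean ~ log(size), data = curve, weights = w)
  cc <- unname(stats::coef(fit)[1])
  d <- unname(stats::coef(fit)[2])
  flags <- character(0)
  if ((expected_sign == "negative" && d >= 0) ||
      (expected_sign == "positive" && d <= 0)) {
    flags <- "wrong_sign_slope"
  }
  list(c = cc, d = d, flags = flags)
}

#' Extrapolate the expected performance at convergence
#'
#' Evaluates the fitted logarithmic performance model at the convergence
#' sample size: `Yec = c + d log(N_c)`, clamped to the metric's range
#' (\eqn{[-1, 1]} for the Youden index, \eqn{[0, 1]} for AUC) with a
#' `clamped` flag.
#'
#' @param perf_fit list from [fit_perf_weighted_log()].
#' @param n_c convergence sample size from the SD fit.
#' @param metric `"youden"` or `"auc"`.
#' @return list with `yec`, `raw`, `flags`.
#' @export
extrapolate_yec <- function(perf_fit, n_c, metric = c("youden", "auc")) {
  metric <- match.arg(metric)
  raw <- perf_fit$c + perf_fit$d * log(n_c)
  rng <- if (metric == "youden") c(-1, 1) else c(0, 1)
  yec <- min(max(raw, rng[1]), rng[2])
  flags <- if (yec != raw) "clamped" else character(0)
  list(yec = yec, raw = raw, flags = flags)
}

#' Smallest sample size from which a performance curve is stable
#'
#' Stability is declared at the smallest size `N_p` from which every pair of
#' consecutive subsets (step S apart) changes the mean performance by at
#' most `tol` in absolute value. With `mode = "single_pair"` only the first
#' consecutive pair is required to be within `tol`.
#'
#' @param sizes ascending integer sizes with a constant step.
#' @param means mean performance at each size.
#' @param tol stability tolerance (default 0.01).
#' @param mode `"all_subsequent"` (default) or `"single_pair"`.
#' @return the smallest stable size, or `NA` if stability is never reached.
#' @export
stability_reached <- function(sizes, means, tol = 0.01,
                              mode = c("all_subsequent", "single_pair")) {
  mode <- match.arg(mode)
  if (length(sizes) < 2L) stop("need at least 2 points")
  steps <- diff(sizes)
  if (any(steps <= 0) || length(unique(steps)) != 1L) {
    stop("sizes must be ascending with a constant step")
  }
  d <- abs(diff(means))
  for (p in seq_along(d)) {
    ok <- if (mode == "all_subsequent") all(d[p:length(d)] <= tol)
          else d[p] <= tol
    if (ok) return(sizes[p])
  }
  NA_integer_
}

#' Predict the achievable performance from a limited cohort
#'
#' The full downsampling prediction: builds the downsampling curve from the
#' available cases, fits the SD-decay model (linear for the univariate
#' analysis, logarithmic for the multivariate one) to obtain the convergence
#' sample size `N_c`, fits the weighted logarithmic performance model, and
#' extrapolates the expected performance at convergence `Yec`. `Yec` is the
#' answer to "what Youden index / AUC could a model reach with enough
#' patients?"; a `Yec` near zero (AUC near 0.5) indicates that the features
#' carry no information relevant to the task.
#'
#' By default the curve starts half a downsampling step below the number of
#' available cases (e.g. 84 out of 88 available at S = 8), so that every
#' size -- including the largest -- is a genuine random subsample with a
#' nonzero run-to-run SD; at most `ceiling(s/2)` cases are set aside.
#'
#' @inheritParams build_downsampling_curve
#' @return An object of class `extrapolation_report`: list with `curve`,
#'   `sd_fit`, `perf_fit`, `n_c`, `yec`, `perf_at_n` (the curve mean at the
#'   full available size, i.e. the estimate one would report without
#'   downsampling), `stable_from`, `metric`, `analysis`, `flags`.
#' @export
predict_performance <- function(cohort, analysis = "roc", feature = NULL,
                                metric = c("youden", "auc"), s = 8L,
                                n_runs = 50L, base_seed = 1L, min_size = 20L,
                                k_folds = NULL, max_size = NULL) {
  metric <- match.arg(metric)
  is_uni <- identical(analysis, "roc")
  max_size <- max_size %||% (n_samples(cohort) - as.integer(ceiling(s / 2)))
  curve <- build_downsampling_curve(cohort, analysis, feature, metric, s,
                                    n_runs, base_seed, min_size, k_folds,
                                    max_size)
  sd_fit <- if (is_uni) fit_sd_linear(curve) else fit_sd_log(curve)
  perf_fit <- fit_perf_weighted_log(
    curve, expected_sign = if (is_uni) "negative" else "positive")
  ex <- extrapolate_yec(perf_fit, sd_fit$n_c, metric)
  asc <- order(curve$size)
  structure(
    list(curve = curve, sd_fit = sd_fit, perf_fit = perf_fit,
         n_c = sd_fit$n_c, yec = ex$yec,
         perf_at_n = curve$mean[which.max(curve$size)],
         stable_from = stability_reached(curve$size[asc], curve$mean[asc]),
         metric = metric, analysis = attr(curve, "analysis"),
         flags = c(sd_fit$flags, perf_fit$flags, ex$flags)),
    class = "extrapolation_report"
  )
}

#' @export
print.extrapolation_report <- function(x, ...) {
  cat(sprintf(
    "<downsampling prediction: %s, metric %s>\n  %d-point curve (sizes %d..%d)\n  N_c = %.1f, Yec = %.3f (without downsampling: %.3f)%s\n",
    x$analysis, x$metric, nrow(x$curve), min(x$curve$size),
    max(x$curve$size), x$n_c, x$yec, x$perf_at_n,
    if (length(x$flags)) paste0("\n  flags: ", paste(x$flags, collapse = ", "))
    else ""))
  invisible(x)
}
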