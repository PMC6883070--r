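# Quality of the downsampling prediction: how close the extrapolated
# performance comes to the large-cohort reference, compared with the naive
# estimate computed on the available patients alone.

#' Quality factors of a downsampling prediction
#'
#' `qf1 = |yec_n - perf_ntot|` measures the error of the extrapolated
#' performance against the large-cohort reference; `qf2 = |perf_n -
#' perf_ntot|` measures the error of the naive estimate obtained from the N
#' available patients without downsampling (the estimate a study would
#' normally report). `win = (qf1 <= qf2)` means the downsampling prediction
#' is the better estimate. For AUC, `within_5pct` records whether the
#' prediction lands within 5% (relative) of the reference.
#'
#' @param yec_n extrapolated performance from the N available patients.
#' @param perf_n performance estimated at N without downsampling.
#' @param perf_ntot reference performance at the full cohort size.
#' @param metric `"youden"` or `"auc"`.
#' @return list of class `quality_report` with `yec_n`, `perf_n`,
#'   `perf_ntot`, `qf1`, `qf2`, `win`, `metric`, `within_5pct` (NA for the
#'   Youden metric).
#' @export
quality_factors <- function(yec_n, perf_n, perf_ntot,
                            metric = c("youden", "auc")) {
  metric <- match.arg(metric)
  qf1 <- abs(yec_n - perf_ntot)
  qf2 <- abs(perf_n - perf_ntot)
  structure(
    list(yec_n = yec_n, perf_n = perf_n, perf_ntot = perf_ntot,
         qf1 = qf1, qf2 = qf2, win = qf1 <= qf2, metric = metric,
         within_5pct = if (metric == "auc") qf1 <= 0.05 * perf_ntot
                       else NA),
    class = "quality_report"
  )
}

#' Sweep the downsampling prediction over available-cohort sizes
#'
#' For each size N in `n_grid` (an experimental condition: "only N patients
#' are available"), runs the full downsampling prediction with the curve's
#' largest size set to N, every size being repeatedly drawn from the
#' reference cohort, and compares the extrapolated performance and the
#' naive at-N estimate to the full-cohort reference via
#' [quality_factors()]. Evaluating each condition in this repeated-draw
#' framework makes both quality factors expectations over draws rather than
#' properties of one particular N-case subset.
#'
#' For the univariate analysis (`analysis = "roc"`) all requested features
#' share each condition's subsamples, so the whole feature-by-condition grid
#' is computed in one pass; the reference is each feature's full-data
#' resubstitution value. For a classifier analysis the reference is the mean
#' cross-validated performance over `ref_runs` repeated fold shuffles on the
#' full cohort.
#'
#' @param cohort a [cohort()] (the full reference cohort, size N_tot).
#' @param analysis `"roc"` or a vector of classifier ids (`"C1"`..`"C9"`).
#' @param features features to sweep (univariate analysis; default all).
#' @param n_grid vector of available-cohort sizes N.
#' @param s downsampling step.
#' @param n_runs draws per subsample size (default 50).
#' @param base_seed integer base seed.
#' @param min_size smallest subsample size in each curve.
#' @param metric `"youden"` or `"auc"`.
#' @param ref_runs repeated fold shuffles for the classifier reference.
#' @param roc_fr_threshold passed to [classifier_spec()] for C4/C8.
#' @return list with `table` (one row per condition x analysis: `n`,
#'   `analysis`, `yec`, `perf_n`, `perf_ntot`, `qf1`, `qf2`, `win`,
#'   `within_5pct`) and `summary` (`pct_win`, `pct_within_5pct`, `n_cells`).
#' @export
sweep_quality <- function(cohort, analysis = "roc", features = NULL,
                          n_grid, s = 3L, n_runs = 50L, base_seed = 1L,
                          min_size = 13L, metric = c("youden", "auc"),
                          ref_runs = 20L, roc_fr_threshold = 0.2) {
  metric <- match.arg(metric)
  rows <- if (identical(analysis, "roc")) {
    sweep_quality_univariate(cohort, features, n_grid, s, n_runs, base_seed,
                             min_size, metric)
  } else {
    sweep_quality_ml(cohort, analysis, n_grid, s, n_runs, base_seed,
                     min_size, metric, ref_runs, roc_fr_threshold)
  }
  list(table = rows,
       summary = list(
         pct_win = 100 * mean(rows$win),
         pct_within_5pct = if (metric == "auc")
           100 * mean(rows$within_5pct) else NA,
         n_cells = nrow(rows)))
}

sweep_quality_univariate <- function(cohort, features, n_grid, s, n_runs,
                                     base_seed, min_size, metric) {
  feat_idx <- resolve_features(cohort, features)
  nf <- length(feat_idx)
  screen <- screen_features(cohort)[feat_idx, ]
  ref <- if (metric == "youden") screen$yi else screen$auc
  if (any(n_grid - min_size < 2 * s)) {
    stop("insufficient patients for extrapolation at N = ",
         min(n_grid[n_grid - min_size < 2 * s]))
  }

  # every condition N is evaluated in the repeated-draw framework: each
  # size is drawn from the reference cohort (nested prefix chains within a
  # run), so all conditions share one master value table over the union of
  # their sizes and both quality factors are means over draws rather than
  # properties of one lucky subset
  all_sizes <- sort(unique(unlist(
    lapply(n_grid, function(n_av) seq(n_av, min_size, by = -s)))),
    decreasing = TRUE)
  vals <- array(NA_real_, c(length(all_sizes), n_runs, nf))
  n <- n_samples(cohort)
  for (i in seq_len(n_runs)) {
    run_seed <- derive_seed(base_seed, "uni_curve", i)
    ord <- with_seed(run_seed, list(
      pos = sample(which(cohort$labels == 1L)),
      neg = sample(which(cohort$labels == 0L))))
    for (p in seq_along(all_sizes)) {
      np <- all_sizes[[p]]
      n_pos_p <- max(1L, min(np - 1L, round(np * cohort$n_pos / n)))
      idx <- c(ord$pos[seq_len(n_pos_p)], ord$neg[seq_len(np - n_pos_p)])
      y <- cohort$labels[idx]
      for (k in seq_len(nf)) {
        v <- cohort$features[idx, feat_idx[k]]
        cut <- youden_optimal_cutoff(v, y)
        vals[p, i, k] <- if (metric == "youden") cut$yi
                         else oriented_auc(v, y, cut$direction)
      }
    }
  }
  means <- apply(vals, c(1, 3), mean)
  sds <- apply(vals, c(1, 3), sd_or_zero)

  out <- vector("list", length(n_grid))
  for (g in seq_along(n_grid)) {
    n_av <- n_grid[[g]]
    rows <- match(seq(n_av, min_size, by = -s), all_sizes)
    out[[g]] <- do.call(rbind, lapply(seq_len(nf), function(k) {
      curve <- data.frame(size = all_sizes[rows], mean = means[rows, k],
                          sd = sds[rows, k])
      sd_fit <- fit_sd_linear(curve)
      perf_fit <- fit_perf_weighted_log(curve, "negative")
      yec <- extrapolate_yec(perf_fit, sd_fit$n_c, metric)$yec
      qf <- quality_factors(yec, curve$mean[1], ref[[k]], metric)
      data.frame(n = n_av, analysis = cohort$feature_names[[feat_idx[k]]],
                 yec = yec, perf_n = qf$perf_n, perf_ntot = qf$perf_ntot,
                 qf1 = qf$qf1, qf2 = qf$qf2, win = qf$win,
                 within_5pct = qf$within_5pct, stringsAsFactors = FALSE)
    }))
  }
  do.call(rbind, out)
}

sweep_quality_ml <- function(cohort, classifier_ids, n_grid, s, n_runs,
                             base_seed, min_size, metric, ref_runs,
                             roc_fr_threshold) {
  full_setup <- setup("full", cohort$n_pos, cohort$n_neg)
  out <- list()
  for (id in classifier_ids) {
    spec <- classifier_spec(id, roc_fr_threshold = roc_fr_threshold)
    ref_agg <- run_ml_setup(cohort, full_setup, spec, n_runs = ref_runs,
                            base_seed = derive_seed(base_seed, "ref", id),
                            score = metric, keep_runs = FALSE)
    ref <- if (metric == "youden") ref_agg$mean_vs else ref_agg$mean_auc_vs
    for (n_av in n_grid) {
      rep_ <- predict_performance(cohort, analysis = spec, metric = metric,
                                  s = s, n_runs = n_runs,
                                  base_seed = base_seed, min_size = min_size,
                                  max_size = n_av)
      qf <- quality_factors(rep_$yec, rep_$perf_at_n, ref, metric)
      out[[length(out) + 1L]] <- data.frame(
        n = n_av, analysis = id, yec = rep_$yec, perf_n = qf$perf_n,
        perf_ntot = qf$perf_ntot, qf1 = qf$qf1, qf2 = qf$qf2, win = qf$win,
        within_5pct = qf$within_5pct, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
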