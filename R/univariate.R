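# Univariate ROC analysis: Mann-Whitney AUC, Youden-optimal cutoffs learned
# on TRS+VS and applied frozen to TES, aggregated over repeated splits.

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a random positive sample scores above a random negative
#' one, with ties counted one half: the Mann-Whitney U statistic normalized
#' by `n_pos * n_neg`.
#'
#' @param values numeric score vector.
#' @param labels binary 0/1 vector (1 = positive class).
#' @return AUC in \eqn{[0, 1]}.
#' @export
auc <- function(values, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("auc requires both classes to be present")
  }
  r <- rank(values)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Youden-optimal cutoff for a single feature
#'
#' Searches all candidate cutoffs -- midpoints between consecutive distinct
#' sorted values, plus minus and plus infinity -- for the one maximizing the
#' Youden index Se + Sp - 1. With `directions = "both"` (the default) both
#' orientations are searched, so features negatively associated with the
#' positive class are handled and the training YI is always >= 0. Samples
#' whose value equals the cutoff count as the positive side under
#' `greater_is_positive` (negative side under `less_is_positive`). Ties are
#' broken by the smallest cutoff, then by `greater_is_positive`.
#'
#' @param values numeric feature vector.
#' @param labels binary 0/1 vector.
#' @param directions `"both"` or `"greater"` (fixed orientation: higher
#'   values called positive).
#' @return list with `cutoff`, `direction` (`"greater_is_positive"` or
#'   `"less_is_positive"`), `yi`, `se`, `sp`.
#' @export
youden_optimal_cutoff <- function(values, labels,
                                  directions = c("both", "greater")) {
  directions <- match.arg(directions)
  labels <- as.integer(labels)
  n <- length(values)
  n_pos <- sum(labels == 1L)
  n_neg <- n - n_pos
  if (n_pos == 0L || n_neg == 0L) {
    stop("youden_optimal_cutoff requires both classes to be present")
  }
  o <- order(values)
  vs <- values[o]
  ys <- labels[o]
  cpos <- cumsum(ys)
  cneg <- seq_len(n) - cpos
  brk <- which(diff(vs) > 0)          # boundaries between distinct values
  at <- c(0L, brk, n)                 # cut after position `at`
  cp <- c(0L, cpos[brk], n_pos)
  cn <- c(0L, cneg[brk], n_neg)
  # greater_is_positive at each candidate: positives are the samples above
  yi_g <- (n_pos - cp) / n_pos + cn / n_neg - 1
  score <- if (directions == "both") abs(yi_g) else yi_g
  t <- which.max(score)               # first max = smallest cutoff
  cutoff <- if (at[t] == 0L) -Inf else if (at[t] == n) Inf else
    (vs[at[t]] + vs[at[t] + 1L]) / 2
  if (directions == "both" && yi_g[t] < 0) {
    list(cutoff = cutoff, direction = "less_is_positive",
         yi = -yi_g[t], se = cp[t] / n_pos, sp = (n_neg - cn[t]) / n_neg)
  } else {
    list(cutoff = cutoff, direction = "greater_is_positive",
         yi = yi_g[t], se = (n_pos - cp[t]) / n_pos, sp = cn[t] / n_neg)
  }
}

#' Apply a frozen cutoff and direction to new data
#'
#' @param values numeric feature vector.
#' @param labels binary 0/1 vector.
#' @param cutoff,direction as returned by [youden_optimal_cutoff()].
#' @return list with `yi`, `se`, `sp` on the new data.
#' @export
apply_cutoff <- function(values, labels, cutoff, direction) {
  labels <- as.integer(labels)
  pred <- if (direction == "greater_is_positive") values >= cutoff
          else values <= cutoff
  se <- mean(pred[labels == 1L])
  sp <- mean(!pred[labels == 0L])
  list(yi = se + sp - 1, se = se, sp = sp)
}

# AUC oriented along a chosen direction (AUC of the score that calls higher
# values positive under that direction).
oriented_auc <- function(values, labels, direction) {
  a <- auc(values, labels)
  if (direction == "less_is_positive") 1 - a else a
}

#' Full-data univariate screen
#'
#' Resubstitution ROC analysis of every feature on the whole cohort: the
#' Youden-optimal cutoff (both orientations) and the AUC oriented along the
#' chosen direction. This is the reference analysis a study with all
#' patients in hand would run.
#'
#' @param cohort a [cohort()].
#' @return data.frame with one row per feature: `feature`, `yi`, `se`, `sp`,
#'   `cutoff`, `direction`, `auc`.
#' @export
screen_features <- function(cohort) {
  rows <- lapply(seq_along(cohort$feature_names), function(j) {
    v <- cohort$features[, j]
    cut <- youden_optimal_cutoff(v, cohort$labels)
    data.frame(feature = cohort$feature_names[[j]], yi = cut$yi,
               se = cut$se, sp = cut$sp, cutoff = cut$cutoff,
               direction = cut$direction,
               auc = oriented_auc(v, cohort$labels, cut$direction),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Repeated-split univariate ROC analysis for one set-up
#'
#' For each of `n_runs` random splits: the Youden-optimal cutoff is learned
#' on TRS+VS (resubstitution), its YI recorded, and the frozen cutoff and
#' direction applied to TES. Aggregates are means and sample standard
#' deviations (n - 1 denominator) over runs.
#'
#' @param cohort a [cohort()].
#' @param setup a [setup()] (TES counts may be 0; TES aggregates are then NA).
#' @param features feature names or indices; default all.
#' @param n_runs number of repeated splits (default 50).
#' @param base_seed integer base seed.
#' @return data.frame with one row per feature: `mean_vs`, `sd_vs`
#'   (TRS+VS Youden), `mean_tes`, `sd_tes`, `mean_auc`, `sd_auc` (TRS+VS
#'   AUC), `mean_se`, `mean_sp`, `n_runs`. A `setup` attribute carries the
#'   set-up id.
#' @export
run_univariate_setup <- function(cohort, setup, features = NULL,
                                 n_runs = 50L, base_seed = 1L) {
  feat_idx <- resolve_features(cohort, features)
  nf <- length(feat_idx)
  yi_vs <- yi_tes <- auc_vs <- se_vs <- sp_vs <- matrix(NA_real_, n_runs, nf)
  has_tes <- setup$n_pos_tes > 0L && setup$n_neg_tes > 0L
  for (i in seq_len(n_runs)) {
    plan <- draw_split(cohort, setup, i, base_seed)
    lab_trvs <- cohort$labels[plan$trvs_indices]
    lab_tes <- cohort$labels[plan$tes_indices]
    for (k in seq_len(nf)) {
      v_trvs <- cohort$features[plan$trvs_indices, feat_idx[k]]
      cut <- youden_optimal_cutoff(v_trvs, lab_trvs)
      yi_vs[i, k] <- cut$yi
      se_vs[i, k] <- cut$se
      sp_vs[i, k] <- cut$sp
      auc_vs[i, k] <- oriented_auc(v_trvs, lab_trvs, cut$direction)
      if (has_tes) {
        v_tes <- cohort$features[plan$tes_indices, feat_idx[k]]
        yi_tes[i, k] <- apply_cutoff(v_tes, lab_tes, cut$cutoff,
                                     cut$direction)$yi
      }
    }
  }
  out <- data.frame(
    feature = cohort$feature_names[feat_idx],
    mean_vs = colMeans(yi_vs), sd_vs = apply(yi_vs, 2, sd_or_zero),
    mean_tes = colMeans(yi_tes), sd_tes = apply(yi_tes, 2, sd_or_zero),
    mean_auc = colMeans(auc_vs), sd_auc = apply(auc_vs, 2, sd_or_zero),
    mean_se = colMeans(se_vs), mean_sp = colMeans(sp_vs),
    n_runs = n_runs, stringsAsFactors = FALSE)
  attr(out, "setup") <- setup$id
  if (n_runs < 2L) attr(out, "degenerate_sd") <- TRUE
  out
}

#' Count features called predictive on TRS+VS and on TES
#'
#' Given per-feature aggregates at one set-up, counts how many features
#' exceed a Youden threshold on the training side (`mean_vs`) and on the test
#' side (`mean_tes`), and their ratio -- a measure of how many apparently
#' predictive features survive independent testing.
#'
#' @param aggregates data.frame from [run_univariate_setup()].
#' @param threshold Youden threshold (e.g. 0.20 for a permissive screen,
#'   0.75 for a most-predictive-features screen).
#' @return list with `n_trvs_selected`, `n_tes_selected`, `ratio` (0 and
#'   `flagged = TRUE` when no feature passes on the training side).
#' @export
count_predictive_features <- function(aggregates, threshold) {
  n_trvs <- sum(aggregates$mean_vs > threshold, na.rm = TRUE)
  n_tes <- sum(aggregates$mean_tes > threshold, na.rm = TRUE)
  if (n_trvs == 0L) {
    list(n_trvs_selected = 0L, n_tes_selected = n_tes, ratio = 0,
         flagged = TRUE)
  } else {
    list(n_trvs_selected = n_trvs, n_tes_selected = n_tes,
         ratio = n_tes / n_trvs, flagged = FALSE)
  }
}

resolve_features <- function(cohort, features) {
  if (is.null(features)) return(seq_along(cohort$feature_names))
  if (is.character(features)) {
    idx <- match(features, cohort$feature_names)
    if (anyNA(idx)) {
      stop("unknown feature(s): ",
           paste(features[is.na(idx)], collapse = ", "))
    }
    idx
  } else {
    as.integer(features)
  }
}
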