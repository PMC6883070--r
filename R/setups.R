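# Experimental set-ups: per-class subset sizes for the training+validation
# and test sets, and the repeated stratified random splits drawn from them.

#' Define an experimental set-up
#'
#' A set-up fixes how many samples of each class enter the training +
#' validation set (TRS+VS, used to build and tune a model) and the test set
#' (TES, used for independent evaluation), plus the number of folds K for the
#' stratified K-fold cross-validation used by the multivariate pipelines. TES
#' counts of zero are allowed (cross-validation-only protocols).
#'
#' @param id short label, e.g. `"S5"`.
#' @param n_pos_trvs,n_neg_trvs per-class TRS+VS sizes.
#' @param n_pos_tes,n_neg_tes per-class TES sizes (default 0).
#' @param k_folds number of folds; defaults to [default_k_folds()] of the
#'   TRS+VS minority count.
#' @return An object of class `setup`.
#' @export
setup <- function(id, n_pos_trvs, n_neg_trvs, n_pos_tes = 0L,
                  n_neg_tes = 0L, k_folds = NULL) {
  counts <- c(n_pos_trvs, n_neg_trvs, n_pos_tes, n_neg_tes)
  if (any(counts < 0)) stop("set-up counts must be >= 0")
  if (n_pos_trvs < 1 || n_neg_trvs < 1) {
    stop("TRS+VS must contain both classes")
  }
  k_folds <- k_folds %||% default_k_folds(min(n_pos_trvs, n_neg_trvs))
  if (k_folds < 2) stop("k_folds must be >= 2")
  if (min(n_pos_trvs, n_neg_trvs) < k_folds) {
    stop("each of the ", k_folds,
         " folds needs at least one sample of the minority class; ",
         "use a smaller K")
  }
  structure(
    list(id = id,
         n_pos_trvs = as.integer(n_pos_trvs),
         n_neg_trvs = as.integer(n_neg_trvs),
         n_pos_tes = as.integer(n_pos_tes),
         n_neg_tes = as.integer(n_neg_tes),
         k_folds = as.integer(k_folds)),
    class = "setup"
  )
}

#' Default number of cross-validation folds
#'
#' `clamp(floor(minority_count / 10), 2, 10)`: keeps roughly ten or more
#' minority-class samples per fold while staying between 2 and 10 folds.
#'
#' @param minority_count TRS+VS size of the smaller class.
#' @return integer fold count.
#' @export
default_k_folds <- function(minority_count) {
  max(2L, min(10L, as.integer(minority_count %/% 10L)))
}

#' Build a grid of experimental set-ups
#'
#' Constructs the increasing sequence of set-ups used to study how estimated
#' performance changes with the number of patients. In `unbalanced` mode both
#' classes grow at the cohort's class ratio (per-class start and step given
#' explicitly as integer pairs, never derived from a float ratio); in
#' `balanced` mode both classes grow equally. The TES is the same for every
#' set-up.
#'
#' @param cohort a [cohort()]; used only to check feasibility.
#' @param start,step integer pairs `c(pos, neg)`: first set-up and per-step
#'   increment.
#' @param n_setups number of set-ups.
#' @param tes integer pair `c(pos, neg)` for the test set.
#' @param k_folds optional integer vector of fold counts (recycled); defaults
#'   to [default_k_folds()] per set-up.
#' @param prefix id prefix, default `"S"`.
#' @return list of [setup()] objects.
#' @export
build_setup_grid <- function(cohort, start, step, n_setups, tes = c(0L, 0L),
                             k_folds = NULL, prefix = "S") {
  grid <- vector("list", n_setups)
  for (s in seq_len(n_setups)) {
    np <- start[[1]] + (s - 1L) * step[[1]]
    nn <- start[[2]] + (s - 1L) * step[[2]]
    if (np + tes[[1]] > cohort$n_pos || nn + tes[[2]] > cohort$n_neg) {
      stop(sprintf(
        "set-up %s%d infeasible: needs %d positive and %d negative samples, cohort has %d/%d",
        prefix, s, np + tes[[1]], nn + tes[[2]], cohort$n_pos, cohort$n_neg))
    }
    k <- if (is.null(k_folds)) NULL else k_folds[[(s - 1L) %% length(k_folds) + 1L]]
    grid[[s]] <- setup(paste0(prefix, s), np, nn, tes[[1]], tes[[2]],
                       k_folds = k)
  }
  grid
}

#' Default set-up grid for the WDBC cohort
#'
#' Eighteen set-ups: nine unbalanced ones growing at the cohort's malignant /
#' benign ratio from 10/17 to 80/136 with a final 160/270 set-up, and nine
#' balanced ones from 10/10 to 80/80 with a final 160/160 set-up. The test
#' set is always 42 malignant / 71 benign.
#'
#' @param cohort the WDBC [cohort()] (or one with the same class counts).
#' @return named list with elements `unbalanced` and `balanced`, each a list
#'   of [setup()] objects.
#' @export
wdbc_setup_grid <- function(cohort = wdbc_cohort()) {
  tes <- c(42L, 71L)
  unb <- build_setup_grid(cohort, start = c(10L, 17L), step = c(10L, 17L),
                          n_setups = 8L, tes = tes)
  unb <- c(unb, list(setup("S9", 160L, 270L, tes[[1]], tes[[2]])))
  bal <- build_setup_grid(cohort, start = c(10L, 10L), step = c(10L, 10L),
                          n_setups = 8L, tes = tes, prefix = "S1")
  # rename balanced ids S10..S17 and append the 160/160 extra set-up
  for (s in seq_along(bal)) bal[[s]]$id <- paste0("S", 9L + s)
  bal <- c(bal, list(setup("S18", 160L, 160L, tes[[1]], tes[[2]])))
  list(unbalanced = unb, balanced = bal)
}

#' Draw one stratified random split for a set-up
#'
#' Samples, without replacement and independently per class, the TRS+VS and
#' TES index sets with exactly the per-class counts of the set-up. The draw
#' is a pure function of `(base_seed, setup$id, run_index)`, so the full grid
#' of repeated splits is reproducible.
#'
#' @param cohort a [cohort()].
#' @param setup a [setup()].
#' @param run_index run number (1-based).
#' @param base_seed integer base seed.
#' @return An object of class `split_plan` with `trvs_indices`,
#'   `tes_indices`, `run_index`, `seed`.
#' @export
draw_split <- function(cohort, setup, run_index, base_seed) {
  need_pos <- setup$n_pos_trvs + setup$n_pos_tes
  need_neg <- setup$n_neg_trvs + setup$n_neg_tes
  if (need_pos > cohort$n_pos || need_neg > cohort$n_neg) {
    stop(sprintf(
      "set-up %s infeasible: needs %d/%d samples per class, cohort has %d/%d",
      setup$id, need_pos, need_neg, cohort$n_pos, cohort$n_neg))
  }
  seed <- derive_seed(base_seed, "split", setup$id, run_index)
  idx <- with_seed(seed, {
    pos <- sample(which(cohort$labels == 1L), need_pos)
    neg <- sample(which(cohort$labels == 0L), need_neg)
    list(pos = pos, neg = neg)
  })
  trvs <- c(idx$pos[seq_len(setup$n_pos_trvs)],
            idx$neg[seq_len(setup$n_neg_trvs)])
  tes <- c(idx$pos[setup$n_pos_trvs + seq_len(setup$n_pos_tes)],
           idx$neg[setup$n_neg_trvs + seq_len(setup$n_neg_tes)])
  structure(
    list(trvs_indices = trvs, tes_indices = tes,
         run_index = as.integer(run_index), seed = seed),
    class = "split_plan"
  )
}

# Stratified draw of m positions from a 0/1 label vector, preserving the
# class ratio (nearest-integer rounding, at least `min_per_class` per class).
stratified_take <- function(labels, m, seed, min_per_class = 1L) {
  n_pos_p <- round(m * sum(labels == 1L) / length(labels))
  n_pos_p <- max(min_per_class, min(m - min_per_class, n_pos_p))
  with_seed(seed, {
    c(sample(which(labels == 1L), n_pos_p),
      sample(which(labels == 0L), m - n_pos_p))
  })
}

# Stratified subsample of a cohort: n_p samples at the cohort's class ratio.
stratified_subsample_idx <- function(cohort, n_p, seed, min_per_class = 1L) {
  stratified_take(cohort$labels, n_p, seed, min_per_class)
}

# Restrict a cohort to a row index set.
subset_cohort <- function(cohort, idx, name = cohort$name) {
  cohort(cohort$features[idx, , drop = FALSE], cohort$labels[idx],
         feature_names = cohort$feature_names, name = name)
}
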