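# Cohort container and I/O: feature tables with a binary class label.

#' Construct a cohort
#'
#' A cohort is a numeric feature matrix (rows = patients or lesions, columns =
#' features) together with a binary class label per row. The positive class is
#' encoded as 1, the negative class as 0; which clinical group counts as
#' positive is chosen when the cohort is loaded, because sensitivity and
#' specificity are not symmetric in that choice even though the Youden index
#' is.
#'
#' @param features numeric matrix, `n_samples x n_features`.
#' @param labels binary vector (0/1) of length `n_samples`.
#' @param feature_names optional character vector of unique feature names;
#'   defaults to the matrix column names.
#' @param name cohort name used in reports.
#' @return An object of class `cohort` with fields `features`, `labels`,
#'   `feature_names`, `name`, `n_pos`, `n_neg`.
#' @export
cohort <- function(features, labels, feature_names = NULL, name = "cohort") {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- as.integer(labels)
  if (nrow(features) != length(labels)) {
    stop("features and labels disagree on the number of samples")
  }
  if (!all(labels %in% c(0L, 1L))) {
    stop("labels must be encoded 0/1")
  }
  if (anyNA(features)) {
    bad <- which(rowSums(is.na(features)) > 0)
    stop("missing feature values in rows: ", paste(bad, collapse = ", "))
  }
  feature_names <- feature_names %||% colnames(features) %||%
    paste0("feature_", seq_len(ncol(features)))
  if (anyDuplicated(feature_names)) stop("feature names must be unique")
  colnames(features) <- feature_names
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be non-empty")
  structure(
    list(features = features, labels = labels,
         feature_names = feature_names, name = name,
         n_pos = n_pos, n_neg = n_neg),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort '%s': %d samples (%d positive / %d negative), %d features>\n",
              x$name, length(x$labels), x$n_pos, x$n_neg,
              ncol(x$features)))
  invisible(x)
}

#' Number of samples in a cohort
#' @param cohort a [cohort()] object.
#' @return integer sample count.
#' @export
n_samples <- function(cohort) length(cohort$labels)

#' Load a cohort from a CSV feature table
#'
#' Two dialects are supported. `generic_csv` expects a header row, one label
#' column and numeric feature columns (decimal point, no comma decimals).
#' `wdbc` expects the 32-column UCI Wisconsin Diagnostic Breast Cancer layout
#' without header: column 1 a case ID (dropped), column 2 the diagnosis
#' (M/B), columns 3-32 thirty numeric features.
#'
#' Rows with missing feature values are rejected by default; with
#' `missing = "impute"` they are filled with the per-feature median instead.
#'
#' @param path path to the CSV file (for `generic_csv`, a vector of paths is
#'   allowed and the parts are concatenated row-wise; all parts must share the
#'   same header).
#' @param label_column name of the label column (generic dialect).
#' @param positive_label label value mapped to the positive class (class 1).
#' @param dialect `"generic_csv"` or `"wdbc"`.
#' @param missing `"reject"` (default) or `"impute"` (per-feature median).
#' @param name cohort name; defaults to the file name.
#' @return A [cohort()].
#' @export
load_cohort <- function(path, label_column = "label", positive_label = NULL,
                        dialect = c("generic_csv", "wdbc"),
                        missing = c("reject", "impute"),
                        name = NULL) {
  dialect <- match.arg(dialect)
  missing <- match.arg(missing)
  for (p in path) if (!file.exists(p)) stop("file not found: ", p)

  if (dialect == "wdbc") {
    df <- utils::read.csv(path[[1]], header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) != 32L) {
      stop("wdbc dialect expects 32 columns (ID, diagnosis, 30 features), got ",
           ncol(df))
    }
    labels_raw <- as.character(df[[2]])
    feat_df <- df[, 3:32]
    wdbc_names <- paste0(
      rep(c("mean", "se", "worst"), each = 10), "_",
      rep(c("radius", "texture", "perimeter", "area", "smoothness",
            "compactness", "concavity", "concave_points", "symmetry",
            "fractal_dimension"), times = 3))
    names(feat_df) <- wdbc_names
    positive_label <- positive_label %||% "M"
  } else {
    parts <- lapply(path, utils::read.csv, header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
    if (length(parts) > 1L) {
      hdr <- lapply(parts, names)
      if (!all(vapply(hdr, identical, logical(1), hdr[[1]]))) {
        stop("all CSV parts must share the same header")
      }
    }
    df <- do.call(rbind, parts)
    if (!label_column %in% names(df)) {
      stop("label column '", label_column, "' not found")
    }
    labels_raw <- as.character(df[[label_column]])
    feat_df <- df[, setdiff(names(df), label_column), drop = FALSE]
  }

  classes <- sort(unique(labels_raw))
  if (length(classes) != 2L) {
    stop("label column must contain exactly 2 classes, found ",
         length(classes), ": ", paste(classes, collapse = ", "))
  }
  positive_label <- positive_label %||% classes[[1]]
  if (!positive_label %in% classes) {
    stop("positive label '", positive_label, "' not present in the data")
  }

  for (j in seq_along(feat_df)) {
    col <- feat_df[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & col != "")
      if (length(bad) > 0) {
        stop("non-numeric value in column '", names(feat_df)[j],
             "', row ", bad[[1]], ": '", col[bad[[1]]], "'")
      }
      feat_df[[j]] <- num
    }
  }
  features <- as.matrix(feat_df)

  if (anyNA(features)) {
    if (missing == "reject") {
      bad <- which(rowSums(is.na(features)) > 0)
      stop("missing feature values in rows: ",
           paste(utils::head(bad, 10), collapse = ", "),
           if (length(bad) > 10) sprintf(" (and %d more)", length(bad) - 10))
    }
    for (j in seq_len(ncol(features))) {
      nas <- is.na(features[, j])
      if (any(nas)) features[nas, j] <- stats::median(features[, j], na.rm = TRUE)
    }
  }

  cohort(features, as.integer(labels_raw == positive_label),
         name = name %||% basename(path[[1]]))
}

#' Write a cohort as a generic CSV
#'
#' The inverse of [load_cohort()] (generic dialect): a header row with one
#' `label` column followed by the feature columns. Feature values are written
#' with full precision so a round trip reproduces the matrix bit-identically.
#'
#' @param cohort a [cohort()].
#' @param path output path.
#' @param positive_label,negative_label strings written for classes 1 and 0.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, positive_label = "pos",
                         negative_label = "neg") {
  df <- data.frame(label = ifelse(cohort$labels == 1L, positive_label,
                                  negative_label),
                   stringsAsFactors = FALSE)
  feat <- as.data.frame(cohort$features)
  # 17 significant digits round-trips an IEEE double exactly
  for (j in seq_along(feat)) feat[[j]] <- sprintf("%.17g", feat[[j]])
  utils::write.csv(cbind(df, feat), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The bundled Wisconsin Diagnostic Breast Cancer cohort
#'
#' Loads the public WDBC table (569 fine-needle-aspiration images, 212
#' malignant / 357 benign, 30 nuclear morphology features) shipped with the
#' package as plain-text CSV parts. The malignant class is the positive
#' class.
#'
#' @return A [cohort()] with 569 samples and 30 features.
#' @export
wdbc_cohort <- function() {
  paths <- system.file("extdata",
                       paste0("wdbc_part", 1:3, ".csv"),
                       package = "downstrap", mustWork = TRUE)
  load_cohort(paths, label_column = "diagnosis", positive_label = "M",
              name = "wdbc")
}

#' Permute class labels while preserving class counts
#'
#' Builds a no-information synthetic cohort from a real one: the feature
#' matrix is untouched and every sample is reassigned to the positive or
#' negative group uniformly at random, with exactly the original class
#' counts. Such a cohort carries, by construction, no information relevant to
#' the classification task and serves as the permutation null for the whole
#' pipeline.
#'
#' @param cohort a [cohort()].
#' @param seed integer seed; the permutation is deterministic given the seed.
#' @return A [cohort()] with permuted labels.
#' @export
permute_labels <- function(cohort, seed) {
  labels <- with_seed(seed, sample(cohort$labels))
  out <- cohort
  out$labels <- labels
  out$name <- paste0(cohort$name, "_permuted")
  out
}

#' Specification of a simulated cohort
#'
#' Class-conditional Gaussian features: feature j is N(0, noise_sd^2) in the
#' negative class and N(effect_sizes[j] * noise_sd, noise_sd^2) in the
#' positive class, so `effect_sizes` are standardized mean differences
#' (Cohen's d). An optional block-correlation descriptor induces equicorrelated
#' blocks of features.
#'
#' @param n_pos,n_neg class sizes (positive integers).
#' @param n_features number of features.
#' @param effect_sizes numeric vector of standardized effects, recycled to
#'   `n_features`; 0 = uninformative.
#' @param correlation optional list of blocks, each
#'   `list(features = <indices>, rho = <within-block correlation>)`.
#' @param noise_sd positive common standard deviation.
#' @param seed integer seed.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_pos, n_neg, n_features,
                            effect_sizes = 0, correlation = NULL,
                            noise_sd = 1, seed = 1L) {
  if (n_pos < 1 || n_neg < 1) stop("group sizes must be positive")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  effect_sizes <- rep_len(effect_sizes, n_features)
  structure(
    list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
         n_features = as.integer(n_features), effect_sizes = effect_sizes,
         correlation = correlation, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

#' Simulate a cohort from a specification
#'
#' @param spec a [simulation_spec()].
#' @param name cohort name.
#' @return A [cohort()] with `n_pos + n_neg` samples; positives first.
#' @export
simulate_cohort <- function(spec, name = "simulated") {
  stopifnot(inherits(spec, "simulation_spec"))
  n <- spec$n_pos + spec$n_neg
  p <- spec$n_features
  feats <- with_seed(spec$seed, {
    z <- matrix(stats::rnorm(n * p), n, p)
    if (!is.null(spec$correlation)) {
      for (blk in spec$correlation) {
        idx <- blk$features
        rho <- blk$rho
        if (rho < 0 || rho >= 1) stop("block correlation must be in [0, 1)")
        shared <- stats::rnorm(n)
        z[, idx] <- sqrt(rho) * shared + sqrt(1 - rho) * z[, idx]
      }
    }
    z
  })
  feats <- feats * spec$noise_sd
  labels <- c(rep(1L, spec$n_pos), rep(0L, spec$n_neg))
  shift <- spec$effect_sizes * spec$noise_sd
  feats[labels == 1L, ] <- sweep(feats[labels == 1L, , drop = FALSE], 2,
                                 shift, "+")
  cohort(feats, labels, name = name)
}
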