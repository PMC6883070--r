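# Independent brute-force oracles used to check the analytic implementations.

# AUC by exhaustive pair counting: P(pos > neg) + 0.5 P(tie).
brute_auc <- function(values, labels) {
  pos <- values[labels == 1]
  neg <- values[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Youden maximum by exhaustive search over every candidate cutoff (midpoints
# of consecutive distinct values plus +/-Inf) and both orientations.
brute_youden <- function(values, labels) {
  u <- sort(unique(values))
  cuts <- c(-Inf, (u[-length(u)] + u[-1]) / 2, Inf)
  best <- -Inf
  for (cc in cuts) {
    for (dir in c("greater_is_positive", "less_is_positive")) {
      pred <- if (dir == "greater_is_positive") values >= cc else values <= cc
      se <- mean(pred[labels == 1])
      sp <- mean(!pred[labels == 0])
      best <- max(best, se + sp - 1)
    }
  }
  best
}

# Stability onset by scanning every suffix.
brute_stability <- function(sizes, means, tol = 0.01) {
  d <- abs(diff(means))
  for (p in seq_along(d)) {
    if (all(d[p:length(d)] <= tol)) return(sizes[p])
  }
  NA_integer_
}

# Closed-form OLS via the normal equations.
ols_oracle <- function(x, y, w = rep(1, length(x))) {
  X <- cbind(1, x)
  unname(solve(t(X) %*% (w * X), t(X) %*% (w * y))[, 1])
}

# Small deterministic cohort builders.
separable_cohort <- function(n_pos = 20, n_neg = 20, seed = 1) {
  simulate_cohort(simulation_spec(n_pos, n_neg, n_features = 3,
                                  effect_sizes = c(10, 0, 0), seed = seed),
                  name = "separable")
}

null_cohort <- function(n_pos = 30, n_neg = 30, n_features = 4, seed = 1) {
  simulate_cohort(simulation_spec(n_pos, n_neg, n_features,
                                  effect_sizes = 0, seed = seed),
                  name = "null")
}
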