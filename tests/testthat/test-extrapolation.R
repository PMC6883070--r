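# Downsampling curves, SD-decay fits, N_c, Yec and the stability scan.

make_curve <- function(sizes, means, sds) {
  structure(data.frame(size = sizes, mean = means, sd = sds),
            class = c("performance_curve", "data.frame"))
}

test_that("downsampling sizes follow N_p = N - (p-1)S down to min_size", {
  co84 <- null_cohort(63, 21, seed = 1)    # 84 cases at a 3:1 ratio
  cv <- build_downsampling_curve(co84, "roc", feature = 1, s = 8,
                                 n_runs = 3, base_seed = 1, min_size = 20)
  expect_equal(cv$size, seq(84, 20, by = -8))
  expect_length(cv$size, 9)

  co36 <- null_cohort(27, 9, seed = 2)
  cv <- build_downsampling_curve(co36, "roc", feature = 1, s = 8,
                                 n_runs = 3, base_seed = 1, min_size = 20)
  expect_equal(cv$size, c(36, 28, 20))

  co20 <- null_cohort(15, 5, seed = 3)
  expect_error(
    build_downsampling_curve(co20, "roc", feature = 1, s = 8, n_runs = 3,
                             base_seed = 1, min_size = 20),
    "insufficient patients")
})

test_that("linear SD fit recovers exact lines and flags degenerate ones", {
  sizes <- c(80, 60, 40, 20)
  cv <- make_curve(sizes, rep(0.5, 4), 0.1 - 0.001 * sizes)
  fit <- fit_sd_linear(cv)
  expect_equal(fit$a, 0.1)
  expect_equal(fit$b, 0.001)
  expect_equal(fit$n_c, 100)
  expect_length(fit$flags, 0)

  flat <- fit_sd_linear(make_curve(sizes, rep(0.5, 4), rep(0.05, 4)))
  expect_true("no_zero_crossing" %in% flat$flags)
  expect_equal(flat$n_c, 10 * 80)

  # OLS against the normal-equations oracle under noise
  for (s in 1:20) {
    set.seed(s)
    sd_true <- 0.2 - 0.0015 * sizes + rnorm(4, sd = 0.01)
    fit <- fit_sd_linear(make_curve(sizes, rep(0.4, 4), sd_true))
    ref <- ols_oracle(sizes, sd_true)
    expect_equal(fit$a, ref[1], tolerance = 1e-10)
    expect_equal(-fit$b, ref[2], tolerance = 1e-10)
  }
})

test_that("logarithmic SD fit finds the analytic root, any log base", {
  sizes <- c(100, 80, 60, 40)
  cv <- make_curve(sizes, rep(0.5, 4), 0.5 - 0.1 * log(sizes))
  fit <- fit_sd_log(cv)
  expect_equal(fit$n_c, exp(5), tolerance = 1e-9)

  neg <- fit_sd_log(make_curve(sizes, rep(0.5, 4), 0.1 + 0.01 * log(sizes)))
  expect_true("no_zero_crossing" %in% neg$flags)

  # base-10 reparametrization leaves N_c unchanged
  sd_v <- 0.4 - 0.08 * log(sizes) + c(0.01, -0.01, 0.005, -0.005)
  fit_e <- fit_sd_log(make_curve(sizes, rep(0.5, 4), sd_v))
  cf10 <- ols_oracle(log10(sizes), sd_v)       # SY = a10 - b10 * log10(N)
  n_c10 <- 10^(cf10[1] / -cf10[2])
  expect_equal(fit_e$n_c, n_c10, tolerance = 1e-9)
})

test_that("weighted logarithmic performance fit recovers exact curves", {
  sizes <- c(90, 70, 50, 30)
  cv <- make_curve(sizes, 0.2 + 0.1 * log(sizes), c(0.05, 0.04, 0.03, 0.02))
  fit <- fit_perf_weighted_log(cv, "positive")
  expect_equal(fit$c, 0.2, tolerance = 1e-10)
  expect_equal(fit$d, 0.1, tolerance = 1e-10)
  expect_length(fit$flags, 0)

  # equal SDs reduce to unweighted OLS
  set.seed(5)
  y <- 0.6 - 0.07 * log(sizes) + rnorm(4, sd = 0.02)
  fit <- fit_perf_weighted_log(make_curve(sizes, y, rep(0.03, 4)), "negative")
  ref <- ols_oracle(log(sizes), y)
  expect_equal(fit$c, ref[1], tolerance = 1e-10)
  expect_equal(fit$d, ref[2], tolerance = 1e-10)

  # a zero-SD point keeps a finite weight through the floor
  fit0 <- fit_perf_weighted_log(make_curve(sizes, y, c(0, 0.03, 0.03, 0.03)),
                                "negative")
  expect_true(is.finite(fit0$c) && is.finite(fit0$d))

  # wrong-sign slope is flagged but returned
  up <- fit_perf_weighted_log(cv, "negative")
  expect_true("wrong_sign_slope" %in% up$flags)
  expect_equal(up$d, 0.1, tolerance = 1e-10)
})

test_that("extrapolation evaluates the model at N_c and clamps to range", {
  ex <- extrapolate_yec(list(c = 0.2, d = 0.1), 100, "youden")
  expect_equal(ex$yec, 0.2 + 0.1 * log(100))
  expect_length(ex$flags, 0)

  cl <- extrapolate_yec(list(c = 0.9, d = 0.2), 10, "youden")
  expect_equal(cl$raw, 0.9 + 0.2 * log(10))
  expect_equal(cl$yec, 1)
  expect_true("clamped" %in% cl$flags)

  neg <- extrapolate_yec(list(c = 0.4, d = 0.3), 2, "auc")
  expect_gte(neg$yec, 0)
})

test_that("coefficients are recovered to numerical precision, small bias under noise", {
  sizes <- seq(120, 40, by = -10)
  a <- 0.15; b <- 0.0008; cc <- 0.3; d <- 0.06
  exact <- make_curve(sizes, cc + d * log(sizes), a - b * sizes)
  expect_equal(fit_sd_linear(exact)$a, a, tolerance = 1e-12)
  expect_equal(fit_sd_linear(exact)$b, b, tolerance = 1e-12)
  pf <- fit_perf_weighted_log(exact, "positive")
  expect_equal(pf$c, cc, tolerance = 1e-10)
  expect_equal(pf$d, d, tolerance = 1e-10)

  est <- sapply(1:50, function(i) {
    set.seed(1000 + i)
    cv <- make_curve(sizes,
                     cc + d * log(sizes) + rnorm(length(sizes), sd = 0.01),
                     pmax(a - b * sizes + rnorm(length(sizes), sd = 0.01),
                          1e-4))
    c(fit_sd_linear(cv)$a, fit_sd_linear(cv)$b,
      fit_perf_weighted_log(cv, "positive")$c,
      fit_perf_weighted_log(cv, "positive")$d)
  })
  bias <- rowMeans(est) - c(a, b, cc, d)
  expect_lt(max(abs(bias)), 0.005)
})

test_that("stability onset equals the brute-force suffix scan", {
  expect_equal(stability_reached(c(40, 48, 56, 64, 72),
                                 c(0.40, 0.45, 0.505, 0.507, 0.509)), 56)
  expect_true(is.na(stability_reached(seq(10, 90, by = 10),
                                      rep(c(0.1, 0.15), length.out = 9))))
  expect_error(stability_reached(c(10, 20, 35), c(1, 1, 1)), "constant step")
  expect_error(stability_reached(40, 0.5), "at least 2")

  set.seed(71)
  for (rep in 1:30) {
    n <- sample(3:10, 1)
    sizes <- seq(20, by = 8, length.out = n)
    means <- cumsum(rnorm(n, sd = 0.02))
    expect_identical(stability_reached(sizes, means),
                     brute_stability(sizes, means))
  }
  # single-pair mode stops at the first quiet pair
  expect_equal(stability_reached(c(10, 20, 30, 40), c(0, 0.005, 0.5, 0.5),
                                 mode = "single_pair"), 10)
})

test_that("curve direction: univariate optimism shrinks, CV performance grows", {
  co <- simulate_cohort(simulation_spec(150, 150, 3,
                                        effect_sizes = c(0.8, 0.8, 0),
                                        seed = 23))
  uni <- build_downsampling_curve(co, "roc", feature = 1, s = 40,
                                  n_runs = 50, base_seed = 11, min_size = 60)
  expect_lt(cor(uni$size, uni$mean, method = "spearman"), 0)

  # the multivariate growth regime needs a problem the linear model cannot
  # saturate at small n: many weakly informative, partly correlated features
  co_ml <- simulate_cohort(simulation_spec(
    150, 150, 30, effect_sizes = 0.25,
    correlation = list(list(features = 1:10, rho = 0.3)), seed = 23))
  ml <- build_downsampling_curve(co_ml, "C1", s = 40, n_runs = 25,
                                 base_seed = 11, min_size = 60, k_folds = 5)
  expect_gt(cor(ml$size, ml$mean, method = "spearman"), 0)
})

test_that("the full prediction report is assembled coherently", {
  co <- simulate_cohort(simulation_spec(90, 90, 4, effect_sizes = 0.9,
                                        seed = 29))
  rep_ <- predict_performance(co, "C9", metric = "youden", s = 20,
                              n_runs = 8, base_seed = 13, min_size = 60)
  expect_s3_class(rep_, "extrapolation_report")
  expect_equal(rep_$perf_at_n, rep_$curve$mean[1])
  expect_equal(rep_$n_c, rep_$sd_fit$n_c)
  expect_true(rep_$yec >= -1 && rep_$yec <= 1)
  expect_output(print(rep_), "downsampling prediction")
})
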