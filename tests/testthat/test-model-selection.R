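test_that("fold assignments partition the samples into near-equal groups", {
  f1 <- make_folds(10, 5, seed = 1)
  expect_equal(sort(unique(f1)), 1:5)
  expect_equal(unname(table(f1)), rep(2L, 5), ignore_attr = TRUE)

  f2 <- make_folds(11, 5, seed = 2)
  expect_equal(sort(unname(c(table(f2)))), c(2L, 2L, 2L, 2L, 3L))

  expect_identical(make_folds(37, 4, seed = 9), make_folds(37, 4, seed = 9))
  # true partition for assorted (n, K, seed)
  for (n in c(7, 23, 50)) for (K in c(2, 3, 5)) {
    f <- make_folds(n, K, seed = n + K)
    expect_length(f, n)
    expect_true(all(f %in% seq_len(K)))
    expect_lte(diff(range(table(f))), 1)
  }
  expect_error(make_folds(4, 5), "K")
})

test_that("the tau grid is equally spaced on (0, tau_max]", {
  # single predictor scaled so tau_max = |x'y| = 20
  x <- matrix(c(3, 4), 2, 1)
  y <- matrix(c(0.8, 0.4) * 2, 2, 1)  # x'y = 2.4*2 + 1.6... fix numerically
  y <- matrix(c(4, 2), 2, 1)          # x'y = 12 + 8 = 20
  A <- matrix(1)
  expect_equal(tau_max(x, y, A), 20)
  expect_equal(default_tau_grid(x, y, A, n_points = 20), as.numeric(1:20))
  expect_equal(default_tau_grid(x, y, A, n_points = 4), c(5, 10, 15, 20))
  g <- default_tau_grid(x, y, A, n_points = 7)
  expect_equal(g[7], 20)
  expect_true(all(diff(g) > 0))
  expect_error(default_tau_grid(x, 0 * y, A), "degenerate")
})

test_that("K-fold MSPE reproduces the hand toy of the prediction-error formula", {
  # two folds of two observations, q = 1, residuals (1, -1) and (2, 0):
  # MSPE = ((1+1)/2 + (4+0)/2) / 2 = 1.5
  fold_resid <- list(c(1, -1), c(2, 0))
  per_fold <- vapply(fold_resid, function(r)
    test_mspe(matrix(r), matrix(0, length(r), 1)), numeric(1))
  expect_equal(mean(per_fold), 1.5)
})

test_that("cross-validated MSPE at tau_max matches the null-model benchmark", {
  d <- generate_dataset(simulation_design(40, 6, 4, s = 3, r = 2, b = 0.5,
                                          rho = 0.2, seed = 14))
  cv <- cv_cisrrr(d$X, d$Y, rank = 2, K = 4, n_tau = 5, seed = 8,
                  final_fit = FALSE)
  # at fraction 1 every fold fits B = 0, predicting the training column means
  bench <- 0
  for (k in 1:4) {
    hold <- cv$folds == k
    mu <- colMeans(d$Y[!hold, , drop = FALSE])
    res <- sweep(d$Y[hold, , drop = FALSE], 2, mu)
    bench <- bench + sum(res^2) / (sum(hold) * ncol(d$Y)) / 4
  }
  expect_equal(cv$mspe[5], bench, tolerance = 1e-10)
})

test_that("cross-validation tunes tau towards good prediction", {
  d <- generate_dataset(sim_case(1, b = 0.4, seed = 15))
  tst <- generate_test_set(d$design, n_test = 500)
  cv <- cv_cisrrr(d$X, d$Y, rank = 5, K = 5, seed = 3)
  expect_s3_class(cv$fit, "cisrrr")
  expect_equal(cv$tau_opt, cv$tau_frac_opt * cv$tau_max)
  expect_equal(which.min(cv$mspe), which(cv$tau_fracs == cv$tau_frac_opt))
  ev <- evaluate_fit(cv$fit, d$C, d$support, tst$X, tst$Y)
  expect_gte(ev$tpr, 0.9)
  # the tuned fit beats the null model by a wide margin
  null_mspe <- test_mspe(tst$Y, matrix(colMeans(d$Y), nrow(tst$Y),
                                       ncol(d$Y), byrow = TRUE))
  expect_lt(ev$mspe, 0.5 * null_mspe)
})

test_that("rank selection recovers an exactly rank-1 signal and clamps the grid", {
  withr::with_seed(16, {
    X <- matrix(rnorm(40 * 6), 40, 6)
    u <- rnorm(6); v <- rnorm(3)
  })
  Y <- X %*% outer(u, v)  # noiseless rank-1, q = 3
  expect_warning(
    rs <- select_rank(X, Y, r_grid = 1:10, K = 4, n_tau = 8, seed = 4),
    "truncated")
  expect_equal(rs$r_hat, 1L)
  expect_lte(max(rs$table$r), 3)
})

test_that("bootstrap stability selection concentrates on real predictors", {
  d <- generate_dataset(simulation_design(60, 8, 4, s = 2, r = 1, b = 2,
                                          rho = 0.1, seed = 23))
  st <- bootstrap_stability(d$X, d$Y, n_boot = 8, freq_cutoff = 0.9,
                            rank = 1, K = 4, n_tau = 10, seed = 5)
  expect_length(st$selection_frequency, 8)
  expect_true(all(st$selection_frequency >= 0 & st$selection_frequency <= 1))
  expect_identical(st$stable_set,
                   which(st$selection_frequency >= 0.9))
  # the strong true predictors are always kept
  expect_true(all(d$support %in% st$stable_set))
  expect_true(all(is.finite(st$per_boot_mspe)))

  # pure-noise responses: nothing should be stable
  withr::with_seed(18, Yn <- matrix(rnorm(60 * 4), 60, 4))
  st0 <- bootstrap_stability(d$X, Yn, n_boot = 8, freq_cutoff = 0.9,
                             rank = 1, K = 4, n_tau = 10, seed = 6)
  expect_length(st0$stable_set, 0)
})
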