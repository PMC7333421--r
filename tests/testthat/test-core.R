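# The group Dantzig solve, its tau_max bound, subspace initialisation and the
# alternating fit.

random_problem <- function(seed, n = 20, p = 6, q = 3, r = 2) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    Y <- matrix(rnorm(n * q), n, q)
  })
  A <- init_subspace_svd_y(Y, r)
  list(X = X, Y = Y, A = A)
}

test_that("tau_max equals the worst row-wise l1 correlation", {
  pr <- random_problem(1)
  expect_equal(tau_max(pr$X, 0 * pr$Y, pr$A), 0)

  withr::with_seed(2, {
    X1 <- matrix(rnorm(10), 10, 1)
    y <- matrix(rnorm(10), 10, 1)
  })
  expect_equal(tau_max(X1, y, matrix(1)), abs(sum(X1 * y)))

  # brute-force loop oracle
  withr::with_seed(3, {
    X <- matrix(rnorm(10 * 5), 10, 5)
    Y <- matrix(rnorm(10 * 3), 10, 3)
  })
  A <- init_subspace_svd_y(Y, 2)
  ref <- 0
  for (j in 1:5) {
    v <- 0
    for (k in 1:2) v <- v + abs(sum(X[, j] * (Y %*% A[, k])))
    ref <- max(ref, v)
  }
  expect_equal(tau_max(X, Y, A), ref)

  expect_error(tau_max(X[1:5, ], Y, A), "row counts")
  expect_error(tau_max(X, Y, A * 2), "orthonormal")
})

test_that("tau at or above tau_max yields the all-zero solution", {
  for (seed in 1:5) {
    pr <- random_problem(seed)
    tm <- tau_max(pr$X, pr$Y, pr$A)
    for (tau in c(tm, 1.5 * tm)) {
      B <- solve_row_sparse_B(pr$X, pr$Y, pr$A, tau)
      expect_true(all(sqrt(rowSums(B^2)) <= 1e-8))
    }
  }
})

test_that("solutions are feasible and match an independent ADMM solve", {
  for (seed in 1:6) {
    pr <- random_problem(seed)
    tau <- 0.45 * tau_max(pr$X, pr$Y, pr$A)
    B <- solve_row_sparse_B(pr$X, pr$Y, pr$A, tau)
    st <- attr(B, "status")
    expect_true(st$converged)
    # feasibility with slack >= -tolerance
    Rm <- crossprod(pr$X, pr$Y %*% pr$A - pr$X %*% B)
    expect_lt(max(rowSums(abs(Rm))), tau * (1 + 1e-6) + 1e-8)
    orc <- oracle_group_dantzig(pr$X, pr$Y, pr$A, tau)
    expect_lt(abs(st$objective - orc$objective), 1e-6)
    expect_lt(max(abs(B - orc$B)), 1e-5)
  }
  expect_error(solve_row_sparse_B(pr$X, pr$Y, pr$A, -1), "nonnegative")
})

test_that("the solution path is sparser for larger tau", {
  for (seed in c(4, 9)) {
    pr <- random_problem(seed, n = 30, p = 10, q = 4, r = 2)
    tm <- tau_max(pr$X, pr$Y, pr$A)
    sizes <- sapply(seq(0.1, 1, by = 0.1), function(f) {
      length(selected_rows(solve_row_sparse_B(pr$X, pr$Y, pr$A, f * tm)))
    })
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("signed permutations of A permute B and preserve the selection", {
  for (seed in 1:10) {
    pr <- random_problem(seed, n = 25, p = 8, q = 4, r = 3)
    tau <- 0.35 * tau_max(pr$X, pr$Y, pr$A)
    B1 <- solve_row_sparse_B(pr$X, pr$Y, pr$A, tau)
    Q <- diag(c(1, -1, 1))[, c(2, 3, 1)]  # signed permutation
    B2 <- solve_row_sparse_B(pr$X, pr$Y, pr$A %*% Q, tau)
    expect_lt(max(abs(B2 - B1 %*% Q)), 1e-6)
    expect_identical(selected_rows(B1), selected_rows(B2))
  }
})

test_that("SVD-of-Y initialisation returns the leading right subspace", {
  # orthogonal columns of distinct norms: the top singular vector is the
  # largest-norm direction
  Y <- cbind(c(3, 0, 0, 0), c(0, 1, 0, 0))
  expect_equal(init_subspace_svd_y(Y, 1), matrix(c(1, 0), 2, 1))

  withr::with_seed(31, Yr <- matrix(rnorm(30 * 10), 30, 10))
  A <- init_subspace_svd_y(Yr, 2)
  expect_equal(crossprod(A), diag(2))
  sv <- svd(Yr)  # full SVD oracle for the best rank-2 row-space projection
  P_ref <- tcrossprod(sv$v[, 1:2])
  expect_lt(max(abs(Yr %*% tcrossprod(A) - Yr %*% P_ref)), 1e-8)

  Af <- init_subspace_svd_y(Yr, 10)
  expect_equal(tcrossprod(Af), diag(10))
  expect_error(init_subspace_svd_y(Yr, 11), "min\\(n, q\\)")
})

test_that("ridge initial estimate agrees across its two computational paths", {
  withr::with_seed(41, Y3 <- matrix(rnorm(9), 3, 3))
  lam <- sqrt(log(3) / 3)
  expect_equal(ridge_coefficients(diag(3), Y3), Y3 / (1 + lam))

  withr::with_seed(42, {
    X <- matrix(rnorm(10 * 50), 10, 50)
    Y <- matrix(rnorm(10 * 4), 10, 4)
  })
  expect_lt(max(abs(ridge_coefficients(X, Y, shortcut = TRUE) -
                    ridge_coefficients(X, Y, shortcut = FALSE))), 1e-8)
  expect_equal(ridge_coefficients(X, 0 * Y), matrix(0, 50, 4))

  # p = 1: lambda = 0 falls back to least squares
  withr::with_seed(43, {
    x <- matrix(rnorm(8), 8, 1)
    y <- matrix(rnorm(8), 8, 1)
  })
  expect_equal(ridge_coefficients(x, y),
               matrix(sum(x * y) / sum(x^2)), tolerance = 1e-10)
})

test_that("subspace from a pilot coefficient estimate is exact and orthonormal", {
  withr::with_seed(51, {
    u <- rnorm(6); v <- rnorm(4)
  })
  C1 <- outer(u, v)
  A1 <- init_subspace_from_c(C1, 1)
  expect_lt(max(abs(C1 %*% tcrossprod(A1) - C1)), 1e-8)

  expect_error(init_subspace_from_c(matrix(0, 4, 3), 1), "degenerate")

  withr::with_seed(52, Ch <- matrix(rnorm(625), 25, 25))
  A5 <- init_subspace_from_c(Ch, 5)
  expect_lt(max(abs(crossprod(A5) - diag(5))), 1e-10)
})

test_that("the alternating fit recovers a noiseless row-sparse rank-1 signal", {
  withr::with_seed(61, {
    X <- matrix(rnorm(40 * 10), 40, 10)
    v <- rnorm(5)
  })
  u <- c(1.2, -0.8, 0.6, rep(0, 7))
  C0 <- outer(u, v)
  Y <- X %*% C0
  A0 <- init_subspace_svd_y(scale(Y, scale = FALSE), 1)
  tm <- tau_max(scale(X, scale = FALSE), scale(Y, scale = FALSE), A0)
  fit <- cisrrr(X, Y, rank = 1, tau = 0.02 * tm)
  expect_true(all(1:3 %in% fit$selected))
  expect_lt(norm(coef(fit) - C0, "F") / norm(C0, "F"), 0.1)
})

test_that("tau above tau_max gives the trivial fit in one alternation", {
  pr <- random_problem(71, n = 30, p = 8, q = 4, r = 2)
  Yc <- scale(pr$Y, scale = FALSE); Xc <- scale(pr$X, scale = FALSE)
  A0 <- init_subspace_svd_y(Yc, 2)
  fit <- cisrrr(pr$X, pr$Y, rank = 2, tau = 1.1 * tau_max(Xc, Yc, A0))
  expect_equal(fit$B, matrix(0, 8, 2))
  expect_equal(fit$C, matrix(0, 8, 4))
  expect_true(fit$converged)
  expect_equal(fit$n_iter, 1L)
  expect_length(fit$selected, 0)
})

test_that("with r = q and A = I the fit reduces to a single solve", {
  pr <- random_problem(81, n = 25, p = 6, q = 3, r = 3)
  tau <- 0.4 * tau_max(pr$X, pr$Y, diag(3))
  fit <- cisrrr(pr$X, pr$Y, rank = 3, tau = tau, A_init = diag(3),
                center = FALSE)
  B_direct <- solve_row_sparse_B(pr$X, pr$Y, diag(3), tau)
  expect_lt(max(abs(fit$B - B_direct)), 1e-7)
})

test_that("refitting from a converged fit does not move the objective", {
  d <- generate_dataset(sim_case(1, b = 0.4, seed = 91))
  Yc <- scale(d$Y, scale = FALSE); Xc <- scale(d$X, scale = FALSE)
  A0 <- init_subspace_svd_y(Yc, 5)
  tau <- 0.2 * tau_max(Xc, Yc, A0)
  fit1 <- cisrrr(d$X, d$Y, rank = 5, tau = tau)
  fit2 <- cisrrr(d$X, d$Y, rank = 5, tau = tau, A_init = fit1$A,
                 warm = list(B = fit1$B, V = fit1$V))
  expect_lt(abs(fit1$objective - fit2$objective), 1e-4)
  expect_identical(fit1$selected, fit2$selected)
})

test_that("row selection thresholds relative to the largest row norm", {
  expect_identical(selected_rows(matrix(0, 4, 2)), integer(0))
  B <- rbind(c(3, 0), c(0, 0), c(1e-12, 0))
  expect_identical(selected_rows(B, rel_threshold = 1e-6), 1L)
  expect_identical(selected_rows(B, rel_threshold = 0), c(1L, 3L))
})

test_that("fit input validation rejects malformed problems", {
  pr <- random_problem(95)
  expect_error(cisrrr(pr$X, pr$Y[1:10, ], rank = 1, tau = 1), "row counts")
  expect_error(cisrrr(pr$X, pr$Y, rank = 0, tau = 1), "rank")
  expect_error(cisrrr(pr$X, pr$Y, rank = 1, tau = -2), "tau")
  Xb <- pr$X; Xb[1, 1] <- NA
  expect_error(cisrrr(Xb, pr$Y, rank = 1, tau = 1), "finite")
})

test_that("prediction restores centres and matches X C for centred data", {
  d <- generate_dataset(sim_case(1, b = 0.4, seed = 96))
  fit <- cisrrr(d$X, d$Y, rank = 5, tau = 0.2 * with(d, {
    Yc <- scale(Y, scale = FALSE); Xc <- scale(X, scale = FALSE)
    tau_max(Xc, Yc, init_subspace_svd_y(Yc, 5))
  }))
  pred <- predict(fit, d$X)
  manual <- sweep(sweep(d$X, 2, fit$x_center) %*% fit$C, 2,
                  fit$y_center, "+")
  expect_equal(pred, manual)
  expect_equal(dim(coef(fit)), c(25, 25))
})
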