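# The row-sparse group Dantzig program:
#   min_B sum_j ||b_j||_2   s.t.   max_j || X_j' (Y A - X B) ||_1 <= tau
# solved by a primal-dual hybrid gradient method (compiled) with a duality-gap
# certificate. tau controls sparsity: larger tau => sparser B, and any
# tau >= tau_max(X, Y, A) makes B = 0 optimal.

#' Solver control parameters
#'
#' @param max_iter maximum primal-dual iterations per solve.
#' @param tol_gap relative duality-gap tolerance (certified bound from a
#'   rescaled dual-feasible point).
#' @param tol_feas relative feasibility tolerance on the worst row-wise l1
#'   constraint violation.
#' @param check_every iterations between convergence checks.
#' @param step_ratio ratio of dual to primal step sizes (both are diagonally
#'   preconditioned; their geometric mean is fixed by the convergence bound).
#'   Values below one favour large primal steps, which empirically converges
#'   fastest on Gram matrices of correlated designs.
#' @return A list of class `cisrrr_control`.
#' @export
solver_control <- function(max_iter = 200000L, tol_gap = 1e-7,
                           tol_feas = 1e-7, check_every = 25L,
                           step_ratio = 0.1) {
  stopifnot(max_iter >= 1, tol_gap > 0, tol_feas > 0, check_every >= 1,
            step_ratio > 0)
  structure(list(max_iter = as.integer(max_iter), tol_gap = tol_gap,
                 tol_feas = tol_feas, check_every = as.integer(check_every),
                 step_ratio = step_ratio),
            class = "cisrrr_control")
}

check_subspace <- function(A, q = NULL, tol = 1e-6) {
  if (!is.matrix(A)) A <- as.matrix(A)
  if (!is.null(q) && nrow(A) != q) stop("`A` has the wrong number of rows")
  g <- crossprod(A)
  if (max(abs(g - diag(ncol(A)))) > tol)
    stop("`A` must have orthonormal columns")
  A
}

#' Upper bound for the sparsity parameter tau
#'
#' Returns `max_j || X_j' Y A ||_1` over predictors j. At or above this value
#' the group Dantzig program admits the trivial solution `B = 0`, so the
#' useful range for `tau` is `(0, tau_max]`.
#'
#' @param X `n x p` predictor matrix.
#' @param Y `n x q` response matrix.
#' @param A `q x r` orthonormal subspace basis.
#' @return A nonnegative scalar.
#' @export
tau_max <- function(X, Y, A) {
  if (nrow(X) != nrow(Y)) stop("`X` and `Y` must have equal row counts")
  A <- check_subspace(A, q = ncol(Y))
  D <- crossprod(X, Y %*% A)
  max(c(rowSums(abs(D)), 0))
}

#' Solve the row-sparse group Dantzig program for fixed subspace A
#'
#' Minimises the sum of row 2-norms of `B` subject to
#' `max_j ||X_j'(Y A - X B)||_1 <= tau`. The solution's nonzero rows identify
#' the selected predictors; for `q = r = 1` the program reduces exactly to the
#' classical Dantzig selector.
#'
#' @inheritParams tau_max
#' @param tau nonnegative constraint bound.
#' @param control a [solver_control()].
#' @param warm optional warm start: list with elements `B` and `V` from a
#'   previous solve on the same problem shape.
#' @return The `p x r` matrix `B`, with a `"status"` attribute (list with
#'   `converged`, `iters`, `gap`, `violation`, `objective`). Non-convergence
#'   within `max_iter` raises a warning and is reported in the status, never
#'   silently returned as zero.
#' @export
solve_row_sparse_B <- function(X, Y, A, tau, control = solver_control(),
                               warm = NULL) {
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0)
    stop("`tau` must be a single nonnegative number")
  if (nrow(X) != nrow(Y)) stop("`X` and `Y` must have equal row counts")
  A <- check_subspace(A, q = ncol(Y))
  S <- crossprod(X)
  D <- crossprod(X, Y %*% A)
  B0 <- if (!is.null(warm$B)) warm$B else matrix(0, 0, 0)
  V0 <- if (!is.null(warm$V)) warm$V else matrix(0, 0, 0)
  res <- .gd_solve(S, D, tau, B0, V0, control$max_iter, control$tol_gap,
                   control$tol_feas, control$check_every,
                   control$step_ratio)
  if (!res$converged)
    warning(sprintf(
      "group Dantzig solve did not reach tolerance in %d iterations (gap %.2e, violation %.2e)",
      control$max_iter, res$gap, res$violation))
  structure(res$B,
            status = list(converged = res$converged, iters = res$iters,
                          gap = res$gap, violation = res$violation,
                          objective = res$objective, V = res$V))
}

#' Solver settings for cross-validation sweeps
#'
#' Cross-validation compares mean squared prediction errors across a tau
#' grid, which needs far less optimisation accuracy than a final fit; these
#' looser tolerances keep full grid sweeps fast while leaving MSPE rankings
#' unchanged. Used as the default by [cv_cisrrr()], [select_rank()],
#' [bootstrap_stability()] and [run_replication_study()].
#'
#' @inheritParams solver_control
#' @return A `cisrrr_control` list.
#' @export
cv_solver_control <- function(max_iter = 20000L, tol_gap = 1e-4,
                              tol_feas = 1e-6, check_every = 25L,
                              step_ratio = 0.1) {
  solver_control(max_iter = max_iter, tol_gap = tol_gap,
                 tol_feas = tol_feas, check_every = check_every,
                 step_ratio = step_ratio)
}
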