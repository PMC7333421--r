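# Initial estimates of the right singular subspace A, and the deterministic
# SVD sign convention used throughout: each singular vector is scaled so its
# largest-magnitude entry is positive (ties broken by lowest index).

svd_sign_fix <- function(V) {
  for (k in seq_len(ncol(V))) {
    i <- which.max(abs(V[, k]))
    if (V[i, k] < 0) V[, k] <- -V[, k]
  }
  V
}

#' Initial subspace from the SVD of Y
#'
#' Returns the top-`r` right singular vectors of `Y`, the sample estimate of
#' the right singular subspace of the response matrix (and hence, under the
#' model, of the coefficient matrix). This is the default initialisation of
#' the alternating algorithm.
#'
#' @param Y `n x q` response matrix.
#' @param r subspace dimension, `1 <= r <= min(n, q)`.
#' @return A `q x r` matrix with orthonormal columns.
#' @export
init_subspace_svd_y <- function(Y, r) {
  Y <- as.matrix(Y)
  if (!(r >= 1 && r <= min(dim(Y))))
    stop("`r` must be between 1 and min(n, q)")
  sv <- svd(Y, nu = 0, nv = r)
  svd_sign_fix(sv$v[, seq_len(r), drop = FALSE])
}

#' Ridge coefficient estimate with the n x n inversion shortcut
#'
#' Computes `solve(t(X) %*% X + lambda * I, t(X) %*% Y)` with
#' `lambda = sqrt(log(p)/n)`. When `n < p` the same quantity is obtained
#' without forming the `p x p` system: with the SVD `X = U D V'` and
#' `R = U D`, the estimate equals `V solve(t(R) R + lambda I, t(R) Y)`,
#' requiring only an `n x n` inversion.
#'
#' @param X `n x p` predictor matrix.
#' @param Y `n x q` response matrix.
#' @param shortcut use the `n x n` path; defaults to `n < p`. Both paths give
#'   identical results and are exposed for verification.
#' @return The `p x q` ridge coefficient matrix. With `p = 1` (`lambda = 0`)
#'   or an otherwise singular system, falls back to the pseudo-inverse
#'   solution (with a warning in the singular case).
#' @export
ridge_coefficients <- function(X, Y, shortcut = nrow(X) < ncol(X)) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X)
  if (nrow(Y) != n) stop("`X` and `Y` must have equal row counts")
  lambda <- sqrt(log(p) / n)
  if (lambda == 0) {  # p = 1: plain least squares via the pseudo-inverse
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-12
    if (!all(pos)) warning("singular system; using the pseudo-inverse")
    di <- ifelse(pos, 1 / sv$d, 0)
    return(sv$v %*% (di * crossprod(sv$u, Y)))
  }
  if (shortcut) {
    sv <- svd(X, nu = min(n, p), nv = min(n, p))
    R <- sv$u %*% diag(sv$d, length(sv$d))
    sv$v %*% solve(crossprod(R) + diag(lambda, ncol(R)), crossprod(R, Y))
  } else {
    solve(crossprod(X) + diag(lambda, p), crossprod(X, Y))
  }
}

#' Initial subspace from the SVD of a coefficient estimate
#'
#' Takes the top-`r` right singular vectors of a (typically ridge-based)
#' pilot estimate of the coefficient matrix.
#'
#' @param C_hat `p x q` coefficient estimate; must be nonzero.
#' @param r subspace dimension, `1 <= r <= min(p, q)`.
#' @return A `q x r` matrix with orthonormal columns.
#' @export
init_subspace_from_c <- function(C_hat, r) {
  C_hat <- as.matrix(C_hat)
  if (!(r >= 1 && r <= min(dim(C_hat))))
    stop("`r` must be between 1 and min(p, q)")
  if (all(C_hat == 0))
    stop("degenerate input: zero coefficient estimate has no singular subspace")
  sv <- svd(C_hat, nu = 0, nv = r)
  svd_sign_fix(sv$v[, seq_len(r), drop = FALSE])
}
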