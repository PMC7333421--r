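# Independent oracles, implemented without touching the package's compiled
# solver path:
#  - admm_group_dantzig(): the same convex program formulated and solved by a
#    structurally different algorithm (ADMM with an exact row-wise l1-ball
#    projection step and an inner block-coordinate-descent group-lasso solve).
#  - dantzig_lp(): the classical Dantzig selector as a linear program
#    (pracma::linprog), exact for the q = r = 1 reduction.
#  - bh_stepup_bruteforce(): the Benjamini-Hochberg step-up rule by direct
#    enumeration over k.

proj_l1_ball_r <- function(v, tau) {
  if (tau <= 0) return(0 * v)
  if (sum(abs(v)) <= tau) return(v)
  u <- sort(abs(v), decreasing = TRUE)
  cs <- cumsum(u)
  k <- seq_along(u)
  theta <- max(((cs - tau) / k)[u > (cs - tau) / k])
  sign(v) * pmax(abs(v) - theta, 0)
}

# min_B sum_j ||b_j||_2  s.t.  ||d_j - (S B)_j||_1 <= tau for every row j,
# via ADMM on the split  S B + U = D,  U row-wise inside the tau l1-ball.
admm_group_dantzig <- function(S, D, tau, rho = NULL, max_iter = 50000L,
                               tol = 1e-10, inner_tol = 1e-12,
                               inner_sweeps = 60L) {
  p <- nrow(S); r <- ncol(D)
  if (is.null(rho)) rho <- 1 / max(abs(S))
  B <- matrix(0, p, r); U <- D; Lam <- matrix(0, p, r)
  s_sq <- colSums(S^2)
  scale_ref <- max(1, sqrt(sum(D^2)))
  for (it in seq_len(max_iter)) {
    # B-step: block coordinate descent on the group-lasso subproblem
    Tm <- D - U - Lam
    R <- Tm - S %*% B
    for (sweep in seq_len(inner_sweeps)) {
      delta <- 0
      for (j in seq_len(p)) {
        bj <- B[j, ]
        Rj <- R + outer(S[, j], bj)
        v <- drop(crossprod(Rj, S[, j]))
        nv <- sqrt(sum(v^2))
        bnew <- if (rho * nv <= 1) rep(0, r)
                else (rho * nv - 1) / (rho * s_sq[j]) * v / nv
        if (any(bnew != bj)) {
          R <- Rj - outer(S[, j], bnew)
          B[j, ] <- bnew
          delta <- max(delta, max(abs(bnew - bj)))
        } else R <- Rj - outer(S[, j], bj)
      }
      if (delta < inner_tol) break
    }
    # U-step: exact projection onto the row-wise l1 ball
    W <- D - S %*% B - Lam
    U_old <- U
    U <- t(apply(W, 1L, proj_l1_ball_r, tau = tau))
    if (r == 1L) U <- matrix(U, p, 1)
    Lam <- Lam + S %*% B + U - D
    pri <- sqrt(sum((S %*% B + U - D)^2)) / scale_ref
    dua <- rho * sqrt(sum((S %*% (U - U_old))^2)) / scale_ref
    if (pri < tol && dua < tol) break
  }
  list(B = B, objective = sum(sqrt(rowSums(B^2))),
       primal_residual = pri, iterations = it)
}

oracle_group_dantzig <- function(X, Y, A, tau, ...) {
  S <- crossprod(X)
  D <- crossprod(X, Y %*% A)
  admm_group_dantzig(S, D, tau, ...)
}

# Classical Dantzig selector: min ||beta||_1 s.t. ||X'(y - X beta)||_inf <= tau
dantzig_lp <- function(X, y, tau) {
  S <- crossprod(X)
  d <- drop(crossprod(X, y))
  p <- ncol(X)
  A <- rbind(cbind(S, -S), cbind(-S, S))
  b <- c(tau + d, tau - d)
  sol <- pracma::linprog(rep(1, 2 * p), A = A, b = b, maxiter = 1000)
  stopifnot(sol$errno == 0 || !is.null(sol$x))
  sol$x[seq_len(p)] - sol$x[p + seq_len(p)]
}

bh_stepup_bruteforce <- function(pvalues, q_level) {
  m <- length(pvalues)
  ord <- order(pvalues)
  ps <- pvalues[ord]
  ks <- which(ps <= seq_len(m) * q_level / m)
  if (length(ks) == 0L) return(integer(0))
  sort(ord[seq_len(max(ks))])
}
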