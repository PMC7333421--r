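# Alternating subspace refinement: given tau and rank r, iterate
#   (i)  B <- argmin sum_j ||b_j||_2  s.t.  max_j ||X_j'(Y A - X B)||_1 <= tau
#   (ii) A <- top-r right singular vectors of X B A'
# until the projector distance ||A A' - A_old A_old'||_F falls below conv_tol.
# The projector distance is invariant to basis rotation, matching the
# coordinate-independence of the estimator: only span(A) matters.

#' Fit a coordinate-independent sparse reduced-rank regression
#'
#' Estimates a row-sparse, rank-`r` coefficient matrix `C = B t(A)` for the
#' multivariate model `Y = X C + E` by alternating a group Dantzig-type
#' convex solve for `B` with an SVD update of the response subspace `A`.
#' Rows of `B` (equivalently of `C`) that are zero drop the corresponding
#' predictor from all `q` response models simultaneously.
#'
#' @param X `n x p` predictor matrix.
#' @param Y `n x q` response matrix.
#' @param rank target rank `r`, `1 <= r <= min(n, q)`.
#' @param tau sparsity bound of the group Dantzig program; see [tau_max()].
#'   Larger values give sparser fits, `tau >= tau_max` gives `B = 0`.
#' @param init initial subspace: `"svd_y"` (top right singular vectors of
#'   `Y`, the default) or `"ridge"` (right singular vectors of a ridge pilot
#'   estimate of `C`).
#' @param center column-centre `X` and `Y` before fitting (the model carries
#'   no intercept); centres are stored and honoured by [predict.cisrrr()].
#' @param scale_x also scale `X` columns to unit standard deviation.
#' @param max_iter maximum alternations.
#' @param conv_tol convergence tolerance on the subspace projector distance.
#' @param control a [solver_control()] for the inner convex solves.
#' @param A_init optional explicit `q x r` orthonormal initial subspace
#'   (overrides `init`).
#' @param warm optional warm start for the inner solver (list with `B`, `V`).
#' @param warn warn when an inner solve stops at `max_iter` short of
#'   tolerance; sweeps that inspect the solver status themselves (as
#'   cross-validation does) disable this.
#' @return An object of class `cisrrr`: list with `B` (`p x r`), `A`
#'   (`q x r`), `C` (`p x q`), `tau`, `rank`, `selected` (indices of nonzero
#'   rows), `objective`, convergence information (`converged`, `degenerate`,
#'   `n_iter`, `trace`), the solver status, and the centring/scaling applied.
#' @seealso [cv_cisrrr()] for tuning `tau`, [select_rank()] for the rank.
#' @export
#' @examples
#' d <- generate_dataset(sim_case(1, b = 0.4, seed = 7))
#' A0 <- init_subspace_svd_y(scale(d$Y, scale = FALSE), 5)
#' tm <- tau_max(scale(d$X, scale = FALSE), scale(d$Y, scale = FALSE), A0)
#' fit <- cisrrr(d$X, d$Y, rank = 5, tau = 0.3 * tm)
#' fit$selected
cisrrr <- function(X, Y, rank, tau, init = c("svd_y", "ridge"),
                   center = TRUE, scale_x = FALSE, max_iter = 50L,
                   conv_tol = 1e-4, control = solver_control(),
                   A_init = NULL, warm = NULL, warn = TRUE) {
  init <- match.arg(init)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (nrow(Y) != n) stop("`X` and `Y` must have equal row counts")
  if (!all(is.finite(X)) || !all(is.finite(Y)))
    stop("`X` and `Y` must be entirely finite")
  if (n < 2) stop("need at least two samples")
  if (!(rank >= 1 && rank <= min(n, q)))
    stop("`rank` must be between 1 and min(n, q)")
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0)
    stop("`tau` must be a single nonnegative number")

  x_center <- if (center) colMeans(X) else rep(0, p)
  y_center <- if (center) colMeans(Y) else rep(0, q)
  x_scale <- rep(1, p)
  Xc <- sweep(X, 2L, x_center)
  if (scale_x) {
    x_scale <- apply(Xc, 2L, sd)
    x_scale[x_scale == 0] <- 1
    Xc <- sweep(Xc, 2L, x_scale, "/")
  }
  Yc <- sweep(Y, 2L, y_center)

  A0 <- if (!is.null(A_init)) check_subspace(A_init, q = q)
        else if (init == "svd_y") init_subspace_svd_y(Yc, rank)
        else init_subspace_from_c(ridge_coefficients(Xc, Yc), rank)

  B0 <- if (!is.null(warm$B)) warm$B else matrix(0, 0, 0)
  V0 <- if (!is.null(warm$V)) warm$V else matrix(0, 0, 0)
  res <- .gd_alternate(Xc, Yc, A0, tau, as.integer(max_iter), conv_tol,
                       control$max_iter, control$tol_gap, control$tol_feas,
                       control$check_every, B0, V0, control$step_ratio)
  if (!res$solver_converged && warn)
    warning("an inner group Dantzig solve did not reach tolerance; ",
            "treat this fit as approximate")

  A <- res$A
  flip <- vapply(seq_len(ncol(A)), function(k) {
    i <- which.max(abs(A[, k]))
    if (A[i, k] < 0) -1 else 1
  }, numeric(1))
  A <- sweep(A, 2L, flip, "*")
  B <- sweep(res$B, 2L, flip, "*")

  structure(list(
    B = B, A = A, C = B %*% t(A), V = res$V,
    tau = tau, rank = as.integer(rank),
    selected = selected_rows(B),
    objective = sum(sqrt(rowSums(B^2))),
    converged = res$converged, degenerate = res$degenerate,
    n_iter = res$outer_iters, inner_iters = res$inner_iters,
    trace = data.frame(objective = res$trace_objective,
                       subspace_distance = res$trace_distance),
    solver = list(converged = res$solver_converged, gap = res$gap,
                  violation = res$violation),
    init = if (!is.null(A_init)) "explicit" else init,
    center = center, x_center = x_center, y_center = y_center,
    scale_x = scale_x, x_scale = x_scale,
    dims = c(n = n, p = p, q = q)), class = "cisrrr")
}

#' Indices of the selected (nonzero) predictor rows
#'
#' Interior-point and first-order solvers return near-zeros rather than exact
#' zeros, so selection thresholds each row 2-norm of `B` relative to the
#' largest row norm.
#'
#' @param B `p x r` coefficient factor (or a `cisrrr` fit).
#' @param rel_threshold relative threshold; a row is selected when its norm
#'   exceeds `rel_threshold * max_j ||b_j||`.
#' @return An integer vector of selected row indices (empty if `B = 0`).
#' @export
selected_rows <- function(B, rel_threshold = 1e-6) {
  if (inherits(B, "cisrrr")) B <- B$B
  stopifnot(rel_threshold >= 0)
  norms <- sqrt(rowSums(as.matrix(B)^2))
  m <- max(norms)
  if (m == 0) return(integer(0))
  which(norms > rel_threshold * m)
}

#' @export
print.cisrrr <- function(x, ...) {
  cat(sprintf("Sparse reduced-rank regression fit (n=%d, p=%d, q=%d)\n",
              x$dims["n"], x$dims["p"], x$dims["q"]))
  cat(sprintf("  rank: %d   tau: %.4g   init: %s\n", x$rank, x$tau, x$init))
  cat(sprintf("  selected predictors: %d of %d\n",
              length(x$selected), x$dims["p"]))
  cat(sprintf("  objective (sum of row norms of B): %.6g\n", x$objective))
  cat(sprintf("  alternations: %d (%s)\n", x$n_iter,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' @export
coef.cisrrr <- function(object, ...) {
  C <- object$C / object$x_scale  # undo predictor scaling
  dimnames(C) <- NULL
  C
}

#' Predict responses from a fitted model
#'
#' @param object a `cisrrr` fit.
#' @param newdata an `n x p` predictor matrix on the original scale.
#' @param ... unused.
#' @return An `n x q` matrix of fitted responses (centres restored).
#' @export
predict.cisrrr <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$dims["p"])
    stop("`newdata` must have ", object$dims["p"], " columns")
  Xc <- sweep(newdata, 2L, object$x_center)
  Xc <- sweep(Xc, 2L, object$x_scale, "/")
  sweep(Xc %*% object$C, 2L, object$y_center, "+")
}

#' Serialise a fit to JSON (plus TSV for the coefficient matrix)
#'
#' @param fit a `cisrrr` fit.
#' @param path output JSON path.
#' @param c_path optional TSV path for the full coefficient matrix `C`.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, c_path = NULL) {
  stopifnot(inherits(fit, "cisrrr"))
  doc <- list(B = fit$B, A = fit$A, tau = fit$tau, rank = fit$rank,
              selected0 = fit$selected - 1L, objective = fit$objective,
              converged = fit$converged, n_iter = fit$n_iter,
              trace = fit$trace, x_center = fit$x_center,
              y_center = fit$y_center, x_scale = fit$x_scale)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  if (!is.null(c_path)) write_matrix(coef(fit), c_path)
  invisible(path)
}

#' Reconstruct a fit from its JSON serialisation
#'
#' Restores the pieces needed for prediction and evaluation (`B`, `A`, `C`,
#' selected set, centres); the convergence trace is carried along verbatim.
#'
#' @param path JSON file written by [write_fit_json()].
#' @return A `cisrrr` object.
#' @export
read_fit_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  B <- as.matrix(doc$B); A <- as.matrix(doc$A)
  structure(list(
    B = B, A = A, C = B %*% t(A), V = NULL,
    tau = doc$tau, rank = as.integer(doc$rank),
    selected = as.integer(doc$selected0) + 1L,
    objective = doc$objective, converged = doc$converged,
    degenerate = FALSE, n_iter = doc$n_iter,
    trace = as.data.frame(doc$trace),
    solver = list(converged = doc$converged, gap = NA_real_,
                  violation = NA_real_),
    init = "restored", center = TRUE,
    x_center = as.numeric(doc$x_center),
    y_center = as.numeric(doc$y_center),
    scale_x = any(doc$x_scale != 1), x_scale = as.numeric(doc$x_scale),
    dims = c(n = NA_integer_, p = nrow(B), q = nrow(A))), class = "cisrrr")
}
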