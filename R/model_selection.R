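# Tuning: K-fold cross-validation of the mean squared prediction error over a
# 20-point grid of tau, rank selection by nested minimisation, and bootstrap
# stability selection.
#
# tau is not comparable across folds (tau_max depends on each fold's training
# data and its initial subspace), so the grid is indexed by *fraction* of the
# fold-specific tau_max: 20 equally spaced fractions in (0, 1], fraction 1
# corresponding to the trivial all-zero fit.

#' Random K-fold assignment
#'
#' @param n number of observations.
#' @param K number of folds, `2 <= K <= n`.
#' @param seed optional seed; with a seed the assignment is reproducible and
#'   the caller's RNG state is untouched.
#' @return An integer vector of length `n` with values in `1:K`; fold sizes
#'   differ by at most one.
#' @export
make_folds <- function(n, K, seed = NULL) {
  if (!(K >= 2 && K <= n)) stop("`K` must satisfy 2 <= K <= n")
  draw <- function() sample(rep_len(seq_len(K), n))
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Equally spaced tau grid on (0, tau_max]
#'
#' @inheritParams tau_max
#' @param n_points grid size (20 in the reference tuning procedure).
#' @return Strictly increasing grid ending exactly at `tau_max`.
#' @export
default_tau_grid <- function(X, Y, A, n_points = 20L) {
  stopifnot(n_points >= 2)
  tm <- tau_max(X, Y, A)
  if (tm <= 0)
    stop("degenerate input: tau_max is zero (X'YA vanishes)")
  seq_len(n_points) / n_points * tm
}

#' Cross-validate the sparsity parameter tau
#'
#' For each fold and each grid fraction, the full pipeline (centring,
#' subspace initialisation, alternating refinement) is run on the held-in
#' data only, and the mean squared prediction error
#' `||X_k C_k - Y_k||_F^2 / (n_k q)` is computed on the held-out fold. The
#' per-fraction MSPE is the average over folds; the optimal tau minimises it,
#' with ties resolved towards the larger (sparser) value. A final fit at the
#' selected tau on the full data is returned unless `final_fit = FALSE`.
#'
#' Fits are warm-started along the grid from sparse to dense; a fold/tau cell
#' whose inner solver fails is treated as missing, not as zero.
#'
#' @inheritParams cisrrr
#' @param K number of folds.
#' @param n_tau grid size.
#' @param folds optional explicit fold assignment from [make_folds()].
#' @param seed seed for the fold draw when `folds` is not given.
#' @param final_fit fit the full-data model at the selected tau.
#' @param warm_state optional environment shared across calls (used by
#'   [select_rank()]): per fold/grid-cell solutions are stored and reused as
#'   warm starts, padded with a zero column when the rank grows by one.
#'   Purely a numerical accelerator; tolerances are unchanged.
#' @return An object of class `cisrrr_cv`: grid fractions, per-fraction MSPE
#'   (and the full fold-by-fraction matrix), `tau_frac_opt`, the full-data
#'   `tau_opt` and `tau_max`, fold assignment, and optionally `fit`.
#' @export
cv_cisrrr <- function(X, Y, rank, K = 5L, n_tau = 20L,
                      init = c("svd_y", "ridge"), folds = NULL, seed = NULL,
                      center = TRUE, scale_x = FALSE, max_iter = 50L,
                      conv_tol = 1e-4, control = cv_solver_control(),
                      final_fit = TRUE, warm_state = NULL) {
  init <- match.arg(init)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (is.null(folds)) folds <- make_folds(n, K, seed = seed)
  K <- max(folds)
  fracs <- seq_len(n_tau) / n_tau
  mspe_folds <- matrix(NA_real_, K, n_tau)

  for (k in seq_len(K)) {
    hold <- folds == k
    Xtr <- X[!hold, , drop = FALSE]; Ytr <- Y[!hold, , drop = FALSE]
    Xte <- X[hold, , drop = FALSE];  Yte <- Y[hold, , drop = FALSE]
    if (nrow(Xtr) < rank)
      stop("training folds must contain at least `rank` observations")
    xc <- if (center) colMeans(Xtr) else rep(0, ncol(X))
    yc <- if (center) colMeans(Ytr) else rep(0, ncol(Y))
    A0 <- if (init == "svd_y")
      init_subspace_svd_y(sweep(Ytr, 2L, yc), rank)
    else
      init_subspace_from_c(
        ridge_coefficients(sweep(Xtr, 2L, xc), sweep(Ytr, 2L, yc)), rank)
    tm <- tau_max(sweep(Xtr, 2L, xc), sweep(Ytr, 2L, yc), A0)
    if (tm <= 0) next
    warm <- NULL
    for (i in rev(seq_len(n_tau))) {  # dense warm start: sparse -> dense
      cell <- paste0(k, ".", i)
      if (!is.null(warm_state) && !is.null(warm_state[[cell]])) {
        ws <- warm_state[[cell]]  # neighbouring-rank solution, zero-padded
        pad <- rank - ncol(ws$B)
        if (pad >= 0)
          warm <- list(B = cbind(ws$B, matrix(0, nrow(ws$B), pad)),
                       V = cbind(ws$V, matrix(0, nrow(ws$V), pad)))
      }
      fit <- tryCatch(
        cisrrr(Xtr, Ytr, rank = rank, tau = fracs[i] * tm, A_init = A0,
               center = center, scale_x = scale_x, max_iter = max_iter,
               conv_tol = conv_tol, control = control, warm = warm,
               warn = FALSE),
        error = function(e) NULL)
      if (is.null(fit)) next
      warm <- list(B = fit$B, V = fit$V)
      if (!is.null(warm_state)) warm_state[[cell]] <- warm
      if (!fit$solver$converged) next
      res <- predict(fit, Xte) - Yte
      mspe_folds[k, i] <- sum(res^2) / (nrow(Yte) * ncol(Yte))
    }
  }

  mspe <- colMeans(mspe_folds, na.rm = TRUE)
  mspe[!is.finite(mspe)] <- NA_real_
  if (all(is.na(mspe))) stop("cross-validation failed on every tau cell")
  best <- max(which(mspe == min(mspe, na.rm = TRUE)))  # ties -> sparser
  out <- list(tau_fracs = fracs, mspe = mspe, mspe_folds = mspe_folds,
              tau_frac_opt = fracs[best], mspe_opt = mspe[best],
              K = K, folds = folds, rank = as.integer(rank), init = init)
  if (final_fit) {
    xc <- if (center) colMeans(X) else rep(0, ncol(X))
    yc <- if (center) colMeans(Y) else rep(0, ncol(Y))
    A0 <- if (init == "svd_y") init_subspace_svd_y(sweep(Y, 2L, yc), rank)
          else init_subspace_from_c(
            ridge_coefficients(sweep(X, 2L, xc), sweep(Y, 2L, yc)), rank)
    out$tau_max <- tau_max(sweep(X, 2L, xc), sweep(Y, 2L, yc), A0)
    out$tau_opt <- fracs[best] * out$tau_max
    out$fit <- cisrrr(X, Y, rank = rank, tau = out$tau_opt, A_init = A0,
                      center = center, scale_x = scale_x,
                      max_iter = max_iter, conv_tol = conv_tol,
                      control = control)
  }
  structure(out, class = "cisrrr_cv")
}

#' @export
print.cisrrr_cv <- function(x, ...) {
  cat(sprintf("%d-fold CV over %d tau fractions (rank %d)\n",
              x$K, length(x$tau_fracs), x$rank))
  cat(sprintf("  optimal fraction of tau_max: %.3g (MSPE %.5g)\n",
              x$tau_frac_opt, x$mspe_opt))
  if (!is.null(x$fit))
    cat(sprintf("  full-data tau_opt: %.5g, %d predictors selected\n",
                x$tau_opt, length(x$fit$selected)))
  invisible(x)
}

#' Select the rank by cross-validation
#'
#' For each candidate rank the tau grid is optimised by [cv_cisrrr()] (same
#' folds throughout), and the rank minimising `MSPE(tau_opt, r)` is chosen;
#' ties go to the smallest rank. Because the inner solver is iterative,
#' exact ties never occur in floating point: ranks whose MSPE is within
#' `tie_tol` times the response variance of the minimum are treated as tied
#' (noiseless data, where every sufficient rank fits exactly, is the
#' motivating case). Candidates exceeding what the fold sizes or the
#' response dimension allow are dropped with a warning.
#'
#' @inheritParams cv_cisrrr
#' @param r_grid candidate ranks (the reference procedure scans 1..10).
#' @param tie_tol relative tie tolerance (in units of the response
#'   variance) under which a smaller rank is preferred.
#' @return An object of class `cisrrr_rank`: `r_hat`, a table of per-rank
#'   minimal MSPE and optimal tau fraction, and the fold assignment.
#' @export
select_rank <- function(X, Y, r_grid = 1:10, K = 5L, n_tau = 20L,
                        init = c("svd_y", "ridge"), folds = NULL, seed = NULL,
                        center = TRUE, scale_x = FALSE, max_iter = 50L,
                        conv_tol = 1e-4, control = cv_solver_control(),
                        tie_tol = 1e-6) {
  init <- match.arg(init)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); q <- ncol(Y)
  if (is.null(folds)) folds <- make_folds(n, K, seed = seed)
  K <- max(folds)
  r_cap <- min(q, min(tabulate(folds, K)) * (K - 1))
  feasible <- r_grid[r_grid <= r_cap]
  if (length(feasible) < length(r_grid))
    warning("rank grid truncated to 1..", r_cap,
            " by the response dimension or fold sizes")
  if (length(feasible) == 0L) stop("no feasible rank in `r_grid`")

  warm_state <- new.env(parent = emptyenv())
  rows <- lapply(feasible, function(r) {
    cv <- cv_cisrrr(X, Y, rank = r, K = K, n_tau = n_tau, init = init,
                    folds = folds, center = center, scale_x = scale_x,
                    max_iter = max_iter, conv_tol = conv_tol,
                    control = control, final_fit = FALSE,
                    warm_state = warm_state)
    data.frame(r = r, mspe = cv$mspe_opt, tau_frac_opt = cv$tau_frac_opt)
  })
  table <- do.call(rbind, rows)
  y_scale <- mean(scale(Y, scale = FALSE)^2)  # response variance sets units
  near <- table$mspe <= min(table$mspe) + tie_tol * y_scale
  r_hat <- min(table$r[near])              # parsimony among numerical ties
  structure(list(r_hat = as.integer(r_hat), table = table, folds = folds,
                 K = K), class = "cisrrr_rank")
}

#' @export
print.cisrrr_rank <- function(x, ...) {
  cat(sprintf("Rank selection by %d-fold CV: r_hat = %d\n", x$K, x$r_hat))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Bootstrap stability selection
#'
#' Draws `n_boot` bootstrap resamples; on each, the rank (unless fixed) and
#' tau are tuned by cross-validation on the resampled training set, the model
#' is fitted, the selected predictors recorded, and the mean squared
#' prediction error evaluated on the out-of-bag rows. The stable set contains
#' predictors selected in at least `freq_cutoff` of the replicates (with the
#' reference settings, at least 45 of 50).
#'
#' @inheritParams cv_cisrrr
#' @param n_boot number of bootstrap replicates.
#' @param freq_cutoff selection-frequency cutoff defining the stable set.
#' @param rank fixed rank; `NULL` re-estimates the rank on every replicate
#'   via [select_rank()] over `r_grid`.
#' @param r_grid candidate ranks when the rank is re-estimated.
#' @param seed base seed; replicate b uses substream `boot<b>`.
#' @return An object of class `cisrrr_stability`: per-predictor
#'   `selection_frequency`, `stable_set`, per-replicate out-of-bag MSPE and
#'   chosen `(r, tau)`.
#' @export
bootstrap_stability <- function(X, Y, n_boot = 50L, freq_cutoff = 0.90,
                                rank = NULL, r_grid = 1:10, K = 5L,
                                n_tau = 20L, init = c("svd_y", "ridge"),
                                seed = 1L, center = TRUE, scale_x = FALSE,
                                max_iter = 50L, conv_tol = 1e-4,
                                control = cv_solver_control()) {
  init <- match.arg(init)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(n_boot >= 1, freq_cutoff >= 0, freq_cutoff <= 1)
  counts <- integer(p)
  oob_mspe <- rep(NA_real_, n_boot)
  r_used <- integer(n_boot)
  tau_used <- numeric(n_boot)

  for (b in seq_len(n_boot)) {
    sub <- substream_seed(seed, paste0("boot", b))
    idx <- with_seed(sub, sample(n, n, replace = TRUE))
    oob <- setdiff(seq_len(n), idx)
    Xb <- X[idx, , drop = FALSE]; Yb <- Y[idx, , drop = FALSE]
    r_b <- if (is.null(rank)) {
      select_rank(Xb, Yb, r_grid = r_grid, K = K, n_tau = n_tau, init = init,
                  seed = substream_seed(sub, "folds"), center = center,
                  scale_x = scale_x, max_iter = max_iter,
                  conv_tol = conv_tol, control = control)$r_hat
    } else as.integer(rank)
    cv <- cv_cisrrr(Xb, Yb, rank = r_b, K = K, n_tau = n_tau, init = init,
                    seed = substream_seed(sub, "folds"), center = center,
                    scale_x = scale_x, max_iter = max_iter,
                    conv_tol = conv_tol, control = control)
    counts[cv$fit$selected] <- counts[cv$fit$selected] + 1L
    r_used[b] <- r_b
    tau_used[b] <- cv$tau_opt
    if (length(oob) > 0) {
      res <- predict(cv$fit, X[oob, , drop = FALSE]) - Y[oob, , drop = FALSE]
      oob_mspe[b] <- sum(res^2) / (length(oob) * ncol(Y))
    } else {
      message("replicate ", b, ": empty out-of-bag set, MSPE skipped")
    }
  }
  freq <- counts / n_boot
  structure(list(n_boot = as.integer(n_boot),
                 selection_frequency = freq,
                 stable_set = which(freq >= freq_cutoff),
                 freq_cutoff = freq_cutoff,
                 per_boot_mspe = oob_mspe, r_used = r_used,
                 tau_used = tau_used), class = "cisrrr_stability")
}

#' @export
print.cisrrr_stability <- function(x, ...) {
  cat(sprintf("Bootstrap stability selection (%d replicates, cutoff %.0f%%)\n",
              x$n_boot, 100 * x$freq_cutoff))
  cat("  stable set:",
      if (length(x$stable_set)) paste(x$stable_set, collapse = ", ")
      else "(empty)", "\n")
  cat(sprintf("  mean out-of-bag MSPE: %.5g\n", mean(x$per_boot_mspe,
                                                     na.rm = TRUE)))
  invisible(x)
}
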