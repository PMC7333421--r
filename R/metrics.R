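# Evaluation quantities of the simulation study: estimation error Delta,
# test-set MSPE, and the variable-selection rates TPR/FPR.

#' Mean squared estimation error of the coefficient matrix
#'
#' `Delta = ||C - C_hat||_F^2 / (p q)`.
#'
#' @param C_true,C_hat `p x q` matrices.
#' @return A nonnegative scalar.
#' @export
delta_error <- function(C_true, C_hat) {
  C_true <- as.matrix(C_true); C_hat <- as.matrix(C_hat)
  if (!identical(dim(C_true), dim(C_hat)))
    stop("`C_true` and `C_hat` must have identical dimensions")
  sum((C_true - C_hat)^2) / prod(dim(C_true))
}

#' Mean squared prediction error on a test set
#'
#' `MSPE = ||Y_t - Y_hat||_F^2 / (n_t q)`.
#'
#' @param Y_test,Y_hat `n_t x q` matrices.
#' @return A nonnegative scalar.
#' @export
test_mspe <- function(Y_test, Y_hat) {
  Y_test <- as.matrix(Y_test); Y_hat <- as.matrix(Y_hat)
  if (!identical(dim(Y_test), dim(Y_hat)))
    stop("`Y_test` and `Y_hat` must have identical dimensions")
  sum((Y_test - Y_hat)^2) / prod(dim(Y_test))
}

check_index_set <- function(set, p, what) {
  set <- as.integer(set)
  if (anyDuplicated(set) || any(set < 1 | set > p))
    stop("`", what, "` must be a subset of 1..p without duplicates")
  set
}

#' True positive rate of variable selection
#'
#' Fraction of truly informative predictors that were selected.
#'
#' @param selected,true_support index sets within `1:p`.
#' @param p number of predictors.
#' @return A value in `[0, 1]`.
#' @export
tpr <- function(selected, true_support, p) {
  selected <- check_index_set(selected, p, "selected")
  true_support <- check_index_set(true_support, p, "true_support")
  if (length(true_support) == 0L)
    stop("TPR is undefined for an empty true support")
  length(intersect(selected, true_support)) / length(true_support)
}

#' False positive rate of variable selection
#'
#' Fraction of uninformative predictors that were selected.
#'
#' @inheritParams tpr
#' @return A value in `[0, 1]`.
#' @export
fpr <- function(selected, true_support, p) {
  selected <- check_index_set(selected, p, "selected")
  true_support <- check_index_set(true_support, p, "true_support")
  if (length(true_support) >= p)
    stop("FPR is undefined when every predictor is informative")
  length(setdiff(selected, true_support)) / (p - length(true_support))
}

#' Evaluate a fit against simulation ground truth
#'
#' @param fit a `cisrrr` fit.
#' @param C_true true `p x q` coefficient matrix.
#' @param true_support indices of the informative rows.
#' @param X_test,Y_test held-out test data (optional; `mspe` is `NA` when
#'   absent).
#' @return A one-row `data.frame` with `delta`, `mspe`, `tpr`, `fpr` and the
#'   selected-set size.
#' @export
evaluate_fit <- function(fit, C_true, true_support,
                         X_test = NULL, Y_test = NULL) {
  stopifnot(inherits(fit, "cisrrr"))
  p <- nrow(C_true)
  mspe <- if (!is.null(X_test) && !is.null(Y_test))
    test_mspe(Y_test, predict(fit, X_test)) else NA_real_
  data.frame(delta = delta_error(C_true, coef(fit)),
             mspe = mspe,
             tpr = tpr(fit$selected, true_support, p),
             fpr = fpr(fit$selected, true_support, p),
             n_selected = length(fit$selected))
}
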