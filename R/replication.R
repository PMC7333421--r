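# End-to-end replication runner for the simulation study: repeated
# generate / tune / fit / evaluate cycles with per-replicate seeds,
# resumable through an on-disk TSV.

#' Run a replicated simulation experiment
#'
#' For each replicate: draw a fresh dataset (seed = `base_seed` + replicate
#' index), tune tau by K-fold cross-validation (optionally also the rank),
#' fit on the full replicate, and evaluate estimation error, test-set MSPE
#' on an independent draw, and selection rates against the true support.
#' A failed replicate is recorded with its error message, never dropped.
#'
#' @param design a [simulation_design()].
#' @param n_reps number of replicates.
#' @param base_seed base seed; replicate i uses `base_seed + i`.
#' @param rank `"fixed"` uses the design's true rank; `"cv"` re-estimates it
#'   per replicate over `r_grid`.
#' @param r_grid candidate ranks for `rank = "cv"`.
#' @param K,n_tau cross-validation settings.
#' @param n_test held-out test-set size for the MSPE.
#' @param out optional TSV path; finished replicates found there are reused,
#'   making the run resumable, and new rows are appended as they complete.
#' @inheritParams cisrrr
#' @return A `data.frame` with one row per replicate: `replicate`, `delta`,
#'   `mspe`, `tpr`, `fpr`, `n_selected`, `tau_opt`, `r`, `status`.
#' @export
run_replication_study <- function(design, n_reps = 50L,
                                  base_seed = design$seed,
                                  rank = c("fixed", "cv"), r_grid = 1:10,
                                  K = 5L, n_tau = 20L, n_test = 10000L,
                                  out = NULL, init = c("svd_y", "ridge"),
                                  max_iter = 50L, conv_tol = 1e-4,
                                  control = cv_solver_control()) {
  stopifnot(inherits(design, "cisrrr_design"))
  rank <- match.arg(rank)
  init <- match.arg(init)
  empty <- data.frame(replicate = integer(0), delta = numeric(0),
                      mspe = numeric(0), tpr = numeric(0), fpr = numeric(0),
                      n_selected = integer(0), tau_opt = numeric(0),
                      r = integer(0), status = character(0))
  done <- empty
  if (!is.null(out) && file.exists(out))
    done <- utils::read.delim(out, stringsAsFactors = FALSE)
  if (n_reps == 0L) {
    if (!is.null(out) && !file.exists(out))
      write.table(empty, out, sep = "\t", row.names = FALSE, quote = FALSE)
    return(if (nrow(done)) done else empty)
  }

  rows <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    if (i %in% done$replicate) {
      rows[[i]] <- done[done$replicate == i, , drop = FALSE]
      next
    }
    row <- tryCatch({
      d_i <- design
      d_i$seed <- as.integer((as.numeric(base_seed) + i) %% 2147483647)
      dat <- generate_dataset(d_i)
      test <- generate_test_set(d_i, n_test = n_test)
      r_i <- if (rank == "fixed") design$r
      else select_rank(dat$X, dat$Y, r_grid = r_grid, K = K, n_tau = n_tau,
                       init = init, seed = substream_seed(d_i$seed, "folds"),
                       max_iter = max_iter, conv_tol = conv_tol,
                       control = control)$r_hat
      cv <- cv_cisrrr(dat$X, dat$Y, rank = r_i, K = K, n_tau = n_tau,
                      init = init, seed = substream_seed(d_i$seed, "folds"),
                      max_iter = max_iter, conv_tol = conv_tol,
                      control = control)
      ev <- evaluate_fit(cv$fit, dat$C, dat$support, test$X, test$Y)
      cbind(data.frame(replicate = i), ev,
            data.frame(tau_opt = cv$tau_opt, r = as.integer(r_i),
                       status = "ok"))
    }, error = function(e) {
      data.frame(replicate = i, delta = NA_real_, mspe = NA_real_,
                 tpr = NA_real_, fpr = NA_real_, n_selected = NA_integer_,
                 tau_opt = NA_real_, r = NA_integer_,
                 status = paste("error:", conditionMessage(e)))
    })
    rows[[i]] <- row
    if (!is.null(out))
      suppressWarnings(write.table(row, out, sep = "\t", row.names = FALSE,
                                   quote = FALSE, append = file.exists(out),
                                   col.names = !file.exists(out)))
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  table
}
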