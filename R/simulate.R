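# Synthetic data with the structure of the simulation study: AR(1) Gaussian
# predictors, a row-sparse rank-r coefficient matrix C = [b * B0 %*% B1; 0],
# and unit-variance noise from one of three families.

#' AR(1) covariance matrix
#'
#' Entry (i, j) equals `rho^|i - j|`: unit diagonal, exponentially decaying
#' correlation with index distance, positive definite for `rho` in `[0, 1)`.
#'
#' @param p dimension (number of predictors).
#' @param rho autocorrelation, in `[0, 1)`.
#' @return A `p x p` covariance matrix.
#' @export
#' @examples
#' ar1_covariance(3, 0.5)
ar1_covariance <- function(p, rho) {
  stopifnot(is.numeric(p), length(p) == 1L, p >= 1)
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho >= 1)
    stop("`rho` must be a single value in [0, 1)")
  idx <- seq_len(p)
  rho^abs(outer(idx, idx, "-"))
}

noise_families <- c("gaussian", "scaled_t5", "tri_uniform")

#' Describe a simulation design
#'
#' Captures every generative parameter of a simulated regression problem:
#' `n` samples of `p` AR(1)-correlated Gaussian predictors, responses
#' `Y = X C + E` with `C` having `s` informative rows (the first `s`, unless
#' permuted) of rank `r` and signal scale `b`, and i.i.d. unit-variance noise.
#'
#' @param n,p,q sample, predictor and response counts.
#' @param s number of informative predictor rows, `0 < s <= p`.
#' @param r true rank, `1 <= r <= min(s, q)`.
#' @param b signal scale, positive.
#' @param rho AR(1) predictor correlation, in `[0, 1)`.
#' @param noise noise family: `"gaussian"`, `"scaled_t5"` (`sqrt(3/5) * t_5`)
#'   or `"tri_uniform"` (sum of three `U[-1, 1]`); all have variance one.
#' @param seed integer seed; every draw is a deterministic function of it.
#' @param permute_support if `TRUE`, the informative rows are a random subset
#'   of `1:p` (drawn under seed control) rather than the leading block.
#' @return An object of class `cisrrr_design`.
#' @export
simulation_design <- function(n, p, q, s, r, b, rho,
                              noise = c("gaussian", "scaled_t5", "tri_uniform"),
                              seed = 1L, permute_support = FALSE) {
  noise <- match.arg(noise)
  stopifnot(n >= 2, p >= 1, q >= 1)
  if (!(s > 0 && s <= p)) stop("need 0 < s <= p")
  if (!(r >= 1 && r <= min(s, q))) stop("need 1 <= r <= min(s, q)")
  if (!(b > 0)) stop("`b` must be positive")
  if (rho < 0 || rho >= 1) stop("`rho` must be in [0, 1)")
  structure(list(n = as.integer(n), p = as.integer(p), q = as.integer(q),
                 s = as.integer(s), r = as.integer(r), b = b, rho = rho,
                 noise = noise, seed = as.integer(seed),
                 permute_support = isTRUE(permute_support)),
            class = "cisrrr_design")
}

#' Preset simulation designs (cases 1-4)
#'
#' The four dimensional regimes of the simulation study:
#' \describe{
#'   \item{1}{`n > p = q`: n=100, p=25, q=25, s=15, r=5, b in \{0.2, 0.4\}}
#'   \item{2}{`q < n < p`: n=30, p=100, q=10, s=15, r=2, b in \{0.5, 1\}}
#'   \item{3}{`n < p = q`: n=30, p=100, q=100, s=15, r=2, b in \{0.5, 1\}}
#'   \item{4}{`n < p < q`: n=30, p=100, q=1000, s=15, r=5, b in \{0.5, 1\}}
#' }
#'
#' @param case integer in 1..4.
#' @param b signal scale; defaults to the smaller value used for that case.
#' @param rho AR(1) correlation (0.1, 0.5 or 0.9 in the study).
#' @inheritParams simulation_design
#' @param ... overrides for individual dimensions (`n`, `p`, `q`, `s`, `r`).
#' @return A `cisrrr_design`.
#' @export
sim_case <- function(case, b = NULL, rho = 0.1,
                     noise = c("gaussian", "scaled_t5", "tri_uniform"),
                     seed = 1L, ...) {
  presets <- list(
    `1` = list(n = 100L, p = 25L,  q = 25L,   s = 15L, r = 5L, b = 0.2),
    `2` = list(n = 30L,  p = 100L, q = 10L,   s = 15L, r = 2L, b = 0.5),
    `3` = list(n = 30L,  p = 100L, q = 100L,  s = 15L, r = 2L, b = 0.5),
    `4` = list(n = 30L,  p = 100L, q = 1000L, s = 15L, r = 5L, b = 0.5))
  key <- as.character(case)
  if (!key %in% names(presets)) stop("`case` must be 1, 2, 3 or 4")
  d <- presets[[key]]
  if (!is.null(b)) d$b <- b
  d[names(list(...))] <- list(...)
  simulation_design(n = d$n, p = d$p, q = d$q, s = d$s, r = d$r, b = d$b,
                    rho = rho, noise = match.arg(noise), seed = seed)
}

#' Row-sparse low-rank coefficient matrix
#'
#' Builds `C = rbind(b * B0 %*% B1, 0)` with `B0` (`s x r`) and `B1` (r-by-q)
#' filled with i.i.d. standard normals drawn from the current RNG stream.
#'
#' @inheritParams simulation_design
#' @param permute_support randomly scatter the informative rows over `1:p`.
#' @return A list with `C` (`p x q`), `support` (sorted indices of the
#'   informative rows) and the factors `B0`, `B1`.
#' @export
make_coefficient_matrix <- function(p, q, s, r, b, permute_support = FALSE) {
  stopifnot(s > 0, s <= p, r >= 1, r <= min(s, q), b >= 0)
  B0 <- matrix(rnorm(s * r), s, r)
  B1 <- matrix(rnorm(r * q), r, q)
  support <- if (permute_support) sort(sample(p, s)) else seq_len(s)
  C <- matrix(0, p, q)
  C[support, ] <- b * (B0 %*% B1)
  list(C = C, support = support, B0 = B0, B1 = B1)
}

#' Unit-variance noise matrix
#'
#' All three families are centred with variance one: standard normal;
#' `sqrt(3/5) * t_5` (Var(t_5) = 5/3); and the sum of three independent
#' `U[-1, 1]` draws (variance 3 * 1/3).
#'
#' @param n,q matrix dimensions.
#' @param family one of `"gaussian"`, `"scaled_t5"`, `"tri_uniform"`.
#' @return An `n x q` matrix of i.i.d. draws.
#' @export
noise_matrix <- function(n, q, family = c("gaussian", "scaled_t5",
                                          "tri_uniform")) {
  family <- match.arg(family)
  m <- n * q
  e <- switch(family,
    gaussian = rnorm(m),
    scaled_t5 = sqrt(3 / 5) * rt(m, df = 5),
    tri_uniform = runif(m, -1, 1) + runif(m, -1, 1) + runif(m, -1, 1))
  matrix(e, n, q)
}

# C and support as a deterministic function of the design (shared by the
# training and test draws).
coef_from_design <- function(design) {
  with_seed(substream_seed(design$seed, "coef"),
            make_coefficient_matrix(design$p, design$q, design$s, design$r,
                                    design$b, design$permute_support))
}

draw_x <- function(n, p, rho, seed) {
  R <- chol(ar1_covariance(p, rho))  # upper triangular, Sigma = t(R) %*% R
  with_seed(seed, matrix(rnorm(n * p), n, p)) %*% R
}

#' Generate a simulated dataset
#'
#' Draws `X` with rows from `N(0, ar1_covariance(p, rho))`, builds the
#' coefficient matrix from the design, and sets `Y = X C + E`. Each component
#' (design matrix, coefficient factors, noise) uses its own named substream of
#' the design seed, so regenerating with the same design is bit-identical and
#' changing the noise family does not perturb `X` or `C`.
#'
#' @param design a [simulation_design()].
#' @param n optional sample-size override (used for test sets).
#' @param stream substream label; the default `"train"` is used for the
#'   fitting data, [generate_test_set()] uses `"test"`.
#' @return An object of class `cisrrr_dataset`: list with `X`, `Y`, `C`,
#'   `support`, `E` and the `design`.
#' @export
generate_dataset <- function(design, n = design$n, stream = "train") {
  stopifnot(inherits(design, "cisrrr_design"))
  cf <- coef_from_design(design)
  X <- draw_x(n, design$p, design$rho,
              substream_seed(design$seed, paste0(stream, ".X")))
  E <- with_seed(substream_seed(design$seed, paste0(stream, ".E")),
                 noise_matrix(n, design$q, design$noise))
  structure(list(X = X, Y = X %*% cf$C + E, C = cf$C, support = cf$support,
                 E = E, design = design),
            class = "cisrrr_dataset")
}

#' Generate a large held-out test set from the same design
#'
#' Same coefficient matrix as [generate_dataset()], fresh predictor and noise
#' draws under a distinct substream. The default size follows the evaluation
#' convention of a 10,000-observation test set.
#'
#' @inheritParams generate_dataset
#' @param n_test test sample size.
#' @export
generate_test_set <- function(design, n_test = 10000L) {
  generate_dataset(design, n = n_test, stream = "test")
}

#' @export
print.cisrrr_design <- function(x, ...) {
  cat(sprintf(
    "Simulation design: n=%d p=%d q=%d s=%d r=%d b=%g rho=%g noise=%s seed=%d\n",
    x$n, x$p, x$q, x$s, x$r, x$b, x$rho, x$noise, x$seed))
  invisible(x)
}

#' Write a simulated dataset to delimited text files
#'
#' Writes `X.tsv`, `Y.tsv`, `C.tsv` (TSV, samples as rows, header row) and
#' `support.txt` (one 0-based row index per line) into `dir`.
#'
#' @param dataset a `cisrrr_dataset`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "cisrrr_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_matrix(dataset$X, file.path(dir, "X.tsv"))
  write_matrix(dataset$Y, file.path(dir, "Y.tsv"))
  write_matrix(dataset$C, file.path(dir, "C.tsv"))
  writeLines(as.character(dataset$support - 1L), file.path(dir, "support.txt"))
  invisible(dir)
}
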