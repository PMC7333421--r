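# Applied pipeline: metabolite QC and transformation, additive genotype
# coding, weighted genetic risk score (GRS), and the two-stage Mendelian-
# randomization screen, runnable end to end on a synthetic cohort.

#' Filter and transform raw metabolite features
#'
#' Drops features with more than `max_zero_frac` zeros or a coefficient of
#' variation (sd/mean on the raw scale, over the positive cells so that the
#' dropout zeros are judged by their own rule) at or above `cv_cut`.
#' Because metabolite intensity distributions are right-skewed,
#' surviving features are log2-transformed -- zero cells first receive half
#' the smallest positive observed value of that feature -- and standardised
#' to mean zero, unit variance. A survivor with zero variance is dropped with
#' a warning.
#'
#' @param raw `n x q` nonnegative matrix of raw feature intensities.
#' @param max_zero_frac maximal tolerated fraction of zeros.
#' @param cv_cut coefficient-of-variation cutoff (0.20 = 20%).
#' @return A list with `data` (the filtered, log2, standardised matrix) and
#'   `kept` (column indices into `raw`).
#' @export
filter_metabolites <- function(raw, max_zero_frac = 0.5, cv_cut = 0.20) {
  raw <- as.matrix(raw)
  if (any(raw < 0)) stop("`raw` must be nonnegative")
  zero_frac <- colMeans(raw == 0)
  cv <- apply(raw, 2L, function(x) {
    x <- x[x > 0]
    if (length(x) < 2 || mean(x) == 0) return(Inf)
    sd(x) / mean(x)
  })
  kept <- which(zero_frac <= max_zero_frac & cv < cv_cut)
  if (length(kept) == 0L)
    return(list(data = matrix(0, nrow(raw), 0), kept = integer(0)))
  sub <- raw[, kept, drop = FALSE]
  logged <- apply(sub, 2L, function(x) {
    if (any(x == 0)) {
      pos <- x[x > 0]
      x[x == 0] <- if (length(pos)) min(pos) / 2 else NA_real_
    }
    log2(x)
  })
  sds <- apply(logged, 2L, sd)
  if (any(sds == 0)) {
    warning(length(which(sds == 0)),
            " feature(s) with zero variance dropped at standardisation")
    kept <- kept[sds > 0]
    logged <- logged[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  data <- scale(logged)
  attr(data, "scaled:center") <- NULL
  attr(data, "scaled:scale") <- NULL
  list(data = data, kept = kept)
}

#' Validate additive (minor-allele count) genotype coding
#'
#' Genotypes are coded 0 (homozygous major), 1 (heterozygote) or 2
#' (homozygous minor) and treated as continuous downstream.
#'
#' @param allele_counts numeric matrix of allele counts.
#' @return An integer matrix with entries in \{0, 1, 2\}.
#' @export
encode_additive <- function(allele_counts) {
  g <- as.matrix(allele_counts)
  ok <- matrix(g %in% c(0, 1, 2), nrow(g), ncol(g))
  bad <- which(!ok, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    shown <- utils::head(bad, 5L)
    stop("invalid genotype values at (row, col): ",
         paste(apply(shown, 1L, paste, collapse = ","), collapse = "; "),
         if (nrow(bad) > 5L) sprintf(" and %d more", nrow(bad) - 5L) else "")
  }
  storage.mode(g) <- "integer"
  g
}

#' Import hard-called genotypes from a VCF
#'
#' Reads the GT field and counts alternate alleles per sample, yielding the
#' 0/1/2 additive coding (the alternate allele is taken as the minor/risk
#' allele). Multi-allelic records and missing calls are rejected.
#'
#' @param path VCF file path.
#' @return An integer matrix, samples as rows, variants as columns (named by
#'   ID when present).
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("the vcfR package is required to import VCF genotypes")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  if (any(grepl(",", alt)))
    stop("multi-allelic records are not supported; split or drop them first")
  gt <- vcfR::extract.gt(v, element = "GT")
  counts <- apply(gt, c(1, 2), function(cell) {
    if (is.na(cell)) return(NA_integer_)
    alleles <- strsplit(cell, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_integer_)
    sum(alleles != "0")
  })
  if (anyNA(counts)) stop("missing genotype calls are not supported")
  m <- t(counts)
  encode_additive(m)
}

#' Per-SNP genetic-risk-score weights from bootstrapped logistic fits
#'
#' For each SNP and each bootstrap resample of the cohort, a single-SNP
#' logistic regression of the binary outcome on the allele count is fitted;
#' the SNP's weight is a weighted mean of the per-replicate log odds ratios
#' (inverse-variance weights by default, plain mean optionally). Replicates
#' showing separation (non-convergence or an extreme/unstable estimate) are
#' excluded and counted.
#'
#' @param genotypes `n x p` additive genotype matrix.
#' @param outcome length-`n` binary vector.
#' @param snp_indices columns to weight (default: all).
#' @param n_boot number of bootstrap replicates.
#' @param weighting `"inverse_variance"` or `"plain"`.
#' @param seed base seed for the bootstrap resamples.
#' @return A list of class `cisrrr_grs_weights`: `snp_indices`, `weights`,
#'   the matrix of per-replicate log odds ratios, and `n_excluded` per SNP.
#' @export
grs_weights <- function(genotypes, outcome, snp_indices = NULL,
                        n_boot = 50L, weighting = c("inverse_variance",
                                                    "plain"), seed = 1L) {
  weighting <- match.arg(weighting)
  G <- encode_additive(genotypes)
  n <- nrow(G)
  stopifnot(length(outcome) == n, all(outcome %in% c(0, 1)), n_boot >= 1)
  if (is.null(snp_indices)) snp_indices <- seq_len(ncol(G))
  if (length(snp_indices) == 0L) stop("`snp_indices` must be nonempty")

  est <- se <- matrix(NA_real_, n_boot, length(snp_indices))
  for (b in seq_len(n_boot)) {
    idx <- with_seed(substream_seed(seed, paste0("grsboot", b)),
                     sample(n, n, replace = TRUE))
    for (s in seq_along(snp_indices)) {
      g <- G[idx, snp_indices[s]]
      y <- outcome[idx]
      fit <- tryCatch(
        withCallingHandlers(
          glm(y ~ g, family = binomial()),
          warning = function(w) invokeRestart("muffleWarning")),
        error = function(e) NULL)
      if (is.null(fit) || !fit$converged || length(coef(fit)) < 2 ||
          is.na(coef(fit)[2])) next
      beta <- coef(fit)[2]
      s_e <- sqrt(diag(vcov(fit)))[2]
      if (!is.finite(beta) || !is.finite(s_e) || abs(beta) > 15 || s_e > 50)
        next  # separation / unstable replicate: excluded
      est[b, s] <- beta
      se[b, s] <- s_e
    }
  }
  weights <- vapply(seq_along(snp_indices), function(s) {
    ok <- is.finite(est[, s])
    if (!any(ok)) return(NA_real_)
    if (weighting == "plain") return(mean(est[ok, s]))
    w <- 1 / se[ok, s]^2
    sum(w * est[ok, s]) / sum(w)
  }, numeric(1))
  structure(list(snp_indices = snp_indices, weights = weights,
                 log_or = est, n_excluded = colSums(!is.finite(est)),
                 weighting = weighting, n_boot = as.integer(n_boot)),
            class = "cisrrr_grs_weights")
}

#' Weighted genetic risk score
#'
#' `score_i = sum_s weight_s * count_is` over the scored SNPs.
#'
#' @param genotypes `n x p` additive genotype matrix.
#' @param weights a numeric vector (paired with `snp_indices`) or a
#'   [grs_weights()] result.
#' @param snp_indices columns scored when `weights` is a plain vector.
#' @return A length-`n` numeric score vector.
#' @export
weighted_grs <- function(genotypes, weights, snp_indices = NULL) {
  G <- encode_additive(genotypes)
  if (inherits(weights, "cisrrr_grs_weights")) {
    snp_indices <- weights$snp_indices
    weights <- weights$weights
  }
  if (is.null(snp_indices)) snp_indices <- seq_len(ncol(G))
  if (length(weights) != length(snp_indices))
    stop("`weights` and `snp_indices` must have equal length")
  drop(G[, snp_indices, drop = FALSE] %*% weights)
}

#' Dichotomize risk scores at an empirical percentile
#'
#' Scores strictly above the stated percentile are coded 1 (high risk), the
#' rest 0; ties at the cutpoint are classified low.
#'
#' @param scores numeric vector.
#' @param percentile percentile in (0, 100); default the 75th.
#' @return An integer 0/1 vector.
#' @export
dichotomize_grs <- function(scores, percentile = 75) {
  stopifnot(all(is.finite(scores)), percentile > 0, percentile < 100)
  as.integer(scores > quantile(scores, percentile / 100))
}

#' Benjamini-Hochberg step-up rejection set
#'
#' Sorts p-values ascending, finds the largest k with
#' `p_(k) <= k * q_level / m`, and rejects the k smallest.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @param q_level target false discovery rate.
#' @return Indices (into `pvalues`) of the rejected hypotheses.
#' @export
bh_fdr <- function(pvalues, q_level) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stopifnot(q_level >= 0, q_level <= 1)
  which(p.adjust(pvalues, method = "BH") <= q_level)
}

#' Two-stage Mendelian-randomization screen
#'
#' Stage 1 regresses each (standardised) metabolite on the genetic risk score
#' adjusted for age and sex; metabolites whose GRS association passes the
#' Benjamini-Hochberg screen at `fdr_threshold` are carried forward, and
#' their stage-1 fitted values serve as the genetically predicted exposure.
#' Stage 2 fits a logistic model of the binary outcome on each predicted
#' exposure (scaled per SD by default, so the odds ratio is per SD of the
#' predicted level), adjusted for age and sex.
#'
#' @param metabolites `n x q` matrix of filtered/standardised features (see
#'   [filter_metabolites()]).
#' @param grs length-`n` genetic risk score; must be non-constant.
#' @param age,sex length-`n` covariates (sex binary).
#' @param outcome length-`n` binary outcome.
#' @param fdr_threshold BH threshold for the stage-1 screen.
#' @param scale_fitted divide stage-1 fitted values by their SD before stage
#'   2, so odds ratios are per SD of the predicted exposure.
#' @return An object of class `cisrrr_mr`: `stage1_pvalues`, `passing_set`,
#'   and a `stage2` data.frame (metabolite index, odds ratio, Wald 95% CI,
#'   p-value); `stage2` is empty when nothing passes.
#' @export
two_stage_mr <- function(metabolites, grs, age, sex, outcome,
                         fdr_threshold = 0.0004, scale_fitted = TRUE) {
  M <- as.matrix(metabolites)
  n <- nrow(M)
  stopifnot(length(grs) == n, length(age) == n, length(sex) == n,
            length(outcome) == n, all(outcome %in% c(0, 1)))
  if (sd(grs) == 0)
    stop("degenerate input: the genetic risk score is constant")

  stage1 <- lapply(seq_len(ncol(M)), function(j) {
    fit <- lm(M[, j] ~ grs + age + sex)
    list(p = summary(fit)$coefficients["grs", "Pr(>|t|)"],
         fitted = fitted(fit))
  })
  pvals <- vapply(stage1, `[[`, numeric(1), "p")
  passing <- bh_fdr(pvals, fdr_threshold)

  stage2 <- do.call(rbind, lapply(passing, function(j) {
    f <- stage1[[j]]$fitted
    if (scale_fitted) f <- f / sd(f)
    fit <- suppressWarnings(glm(outcome ~ f + age + sex,
                                family = binomial()))
    co <- summary(fit)$coefficients
    data.frame(metabolite = j,
               or = exp(co["f", "Estimate"]),
               ci_lower = exp(co["f", "Estimate"] - 1.96 * co["f", "Std. Error"]),
               ci_upper = exp(co["f", "Estimate"] + 1.96 * co["f", "Std. Error"]),
               p_value = co["f", "Pr(>|z|)"])
  }))
  if (is.null(stage2))
    stage2 <- data.frame(metabolite = integer(0), or = numeric(0),
                         ci_lower = numeric(0), ci_upper = numeric(0),
                         p_value = numeric(0))
  structure(list(stage1_pvalues = pvals, passing_set = passing,
                 fdr_threshold = fdr_threshold, stage2 = stage2),
            class = "cisrrr_mr")
}

#' @export
print.cisrrr_mr <- function(x, ...) {
  cat(sprintf("Two-stage MR screen: %d of %d metabolites pass BH at %g\n",
              length(x$passing_set), length(x$stage1_pvalues),
              x$fdr_threshold))
  if (nrow(x$stage2)) print(x$stage2, row.names = FALSE)
  invisible(x)
}

#' Default planted-effect specification for the synthetic cohort
#'
#' Encodes a GRS -> metabolite -> outcome causal chain: `causal_snps` shift
#' the log2 level of `causal_metabolites` by `snp_effect` per minor allele,
#' and each causal metabolite raises the outcome log-odds by `outcome_effect`
#' per SD of its log2 level. Empty index sets give a fully null cohort.
#'
#' @param p_snps,q_metab cohort dimensions.
#' @param causal_snps,causal_metabolites index sets of the planted chain.
#' @param snp_effect per-allele shift of log2 metabolite level. The default
#'   is sized so that genetically driven features keep a raw-scale
#'   coefficient of variation below the 20% QC cutoff, as real post-QC
#'   metabolomics features do.
#' @param outcome_effect per-SD log-odds effect on the outcome.
#' @param age_effect,sex_effect log-odds effects of (age - 50)/10 and sex.
#' @param intercept baseline outcome log-odds.
#' @return A list consumed by [generate_cohort()].
#' @export
cohort_effects <- function(p_snps, q_metab, causal_snps = integer(0),
                           causal_metabolites = integer(0),
                           snp_effect = 0.1, outcome_effect = 1.0,
                           age_effect = 0.3, sex_effect = 0.2,
                           intercept = -1.0) {
  snp_to_metab <- matrix(0, p_snps, q_metab)
  if (length(causal_snps) && length(causal_metabolites))
    snp_to_metab[causal_snps, causal_metabolites] <- snp_effect
  beta <- numeric(q_metab)
  beta[causal_metabolites] <- outcome_effect
  list(snp_to_metab = snp_to_metab, metab_to_outcome = beta,
       age_effect = age_effect, sex_effect = sex_effect,
       intercept = intercept,
       causal_snps = causal_snps, causal_metabolites = causal_metabolites)
}

#' Generate a synthetic cohort for the downstream pipeline
#'
#' A deliberately simple stand-in for a genotype/metabolomics cohort:
#' genotypes are independent `Binomial(2, MAF)` draws; metabolite log2
#' levels are a feature-specific baseline plus planted genotype effects plus
#' Gaussian noise, exponentiated to the raw scale with optional dropout
#' zeros; the binary outcome (high vs low 10-year ASCVD risk) follows a
#' logistic model on the standardised log2 levels of the causal metabolites,
#' age and sex. All planted effects are recorded as ground truth.
#'
#' @param n sample count.
#' @param p_snps,q_metab numbers of SNPs and metabolite features.
#' @param causal a [cohort_effects()] list; default fully null.
#' @param maf minor-allele frequencies, scalar or length `p_snps`, in
#'   `(0, 0.5]`; default drawn uniformly on `[0.1, 0.5]` under the seed.
#' @param zero_rate probability a raw metabolite cell drops to zero.
#' @param noise_sd SD of the log2-scale metabolite noise; the default 0.15
#'   mimics low-CV features that survive the 20% coefficient-of-variation
#'   quality filter.
#' @param seed integer seed (named substreams per component).
#' @return An object of class `cisrrr_cohort`: `genotypes`, raw
#'   `metabolites`, `age`, `sex`, `outcome`, `maf` and the `truth` list.
#' @export
generate_cohort <- function(n, p_snps, q_metab,
                            causal = cohort_effects(p_snps, q_metab),
                            maf = NULL, zero_rate = 0.05, noise_sd = 0.15,
                            seed = 1L) {
  stopifnot(n >= 2, p_snps >= 1, q_metab >= 1)
  if (is.null(maf))
    maf <- with_seed(substream_seed(seed, "maf"), runif(p_snps, 0.1, 0.5))
  maf <- rep_len(maf, p_snps)
  if (any(maf <= 0 | maf > 0.5)) stop("`maf` must lie in (0, 0.5]")

  G <- with_seed(substream_seed(seed, "geno"),
                 matrix(rbinom(n * p_snps, 2L, rep(maf, each = n)),
                        n, p_snps))
  age <- with_seed(substream_seed(seed, "age"), rnorm(n, 50, 10))
  sex <- with_seed(substream_seed(seed, "sex"), rbinom(n, 1L, 0.5))

  mu <- with_seed(substream_seed(seed, "basal"), runif(q_metab, 4, 10))
  noise <- with_seed(substream_seed(seed, "metab"),
                     matrix(rnorm(n * q_metab, 0, noise_sd), n, q_metab))
  L <- matrix(mu, n, q_metab, byrow = TRUE) + G %*% causal$snp_to_metab +
    noise
  raw <- 2^L
  if (zero_rate > 0) {
    mask <- with_seed(substream_seed(seed, "zeros"),
                      matrix(runif(n * q_metab) < zero_rate, n, q_metab))
    raw[mask] <- 0
  }

  Z <- scale(L)
  lp <- causal$intercept + drop(Z %*% causal$metab_to_outcome) +
    causal$age_effect * (age - 50) / 10 + causal$sex_effect * sex
  outcome <- with_seed(substream_seed(seed, "outcome"),
                       rbinom(n, 1L, plogis(lp)))

  structure(list(genotypes = G, metabolites = raw, age = age, sex = sex,
                 outcome = outcome, maf = maf, log2_levels = L,
                 truth = causal, seed = as.integer(seed)),
            class = "cisrrr_cohort")
}

#' Write a cohort to delimited text files
#'
#' `genotypes.tsv`, `metabolites.tsv` and `covariates.tsv` (age, sex,
#' outcome) under `dir`.
#'
#' @param cohort a `cisrrr_cohort`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cisrrr_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_matrix(cohort$genotypes, file.path(dir, "genotypes.tsv"))
  write_matrix(cohort$metabolites, file.path(dir, "metabolites.tsv"))
  cov <- cbind(age = cohort$age, sex = cohort$sex, outcome = cohort$outcome)
  write_matrix(cov, file.path(dir, "covariates.tsv"))
  invisible(dir)
}
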