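test_that("metabolite filtering applies the zero and CV rules then standardises", {
  # q = 3: feature 1 clean, feature 2 has 60% zeros, feature 3 has CV ~ 0.41
  raw <- cbind(c(9, 10, 11, 10, 10),
               c(0, 0, 0, 5, 6),
               c(5, 10, 15, 10, 10))
  expect_gt(sd(raw[, 3]) / mean(raw[, 3]), 0.2)  # hand rule check
  out <- filter_metabolites(raw)
  expect_equal(out$kept, 1L)
  expect_lt(abs(mean(out$data[, 1])), 1e-12)
  expect_equal(sd(out$data[, 1]), 1)

  # constant positive feature: CV = 0 keeps it, zero variance then drops it
  raw2 <- cbind(c(9, 10, 11, 10, 10), rep(7, 5))
  expect_warning(out2 <- filter_metabolites(raw2), "zero variance")
  expect_equal(out2$kept, 1L)

  # zeros in a surviving feature get half the smallest positive value
  raw3 <- cbind(c(0, 10, 10.5, 9.5, 10))
  out3 <- filter_metabolites(raw3, max_zero_frac = 0.5, cv_cut = 10)
  logged <- log2(c(9.5 / 2, 10, 10.5, 9.5, 10))
  expect_equal(out3$data[, 1], as.vector(scale(logged)))
  expect_error(filter_metabolites(-raw), "nonnegative")
})

test_that("additive genotype coding validates and reports offenders", {
  expect_equal(encode_additive(matrix(0, 3, 2)), matrix(0L, 3, 2))
  expect_equal(encode_additive(matrix(1, 4, 1)), matrix(1L, 4, 1))
  m <- matrix(c(0, 1, 2, 1, 0, 2), 3, 2)
  expect_identical(encode_additive(m), matrix(as.integer(m), 3, 2))
  bad <- m; bad[2, 1] <- 3
  expect_error(encode_additive(bad), "2,1")
})

test_that("VCF hard calls import as minor-allele counts", {
  skip_if_not_installed("vcfR")
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0|1\t0/0\t0/1")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  g <- read_genotypes_vcf(path)
  expect_equal(unname(g), rbind(c(0L, 1L), c(1L, 0L), c(2L, 1L)),
               ignore_attr = TRUE)

  multi <- c(vcf[1:4], "1\t300\trs3\tC\tT,G\t.\tPASS\t.\tGT\t0/1\t0/2\t0/0")
  path2 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(multi, path2)
  expect_error(read_genotypes_vcf(path2), "multi-allelic")
})

test_that("GRS weights are near zero for null SNPs and tolerate separation", {
  co <- generate_cohort(800, p_snps = 3, q_metab = 2, seed = 30)
  w <- grs_weights(co$genotypes, co$outcome, n_boot = 12, seed = 2)
  # no planted effects: log odds ratios within 3 SE of zero
  for (s in 1:3) {
    ests <- w$log_or[is.finite(w$log_or[, s]), s]
    expect_lt(abs(w$weights[s]), 3 * sd(ests) + 0.15)
  }
  # inverse-variance and plain means agree when variances are near-equal
  wp <- grs_weights(co$genotypes, co$outcome, n_boot = 12,
                    weighting = "plain", seed = 2)
  expect_lt(max(abs(w$weights - wp$weights)), 0.1)

  # deterministic outcome: separation is excluded, not fatal
  g <- matrix(c(rep(0L, 10), rep(1L, 5), rep(2L, 5)), 20, 1)
  y <- as.integer(g[, 1] >= 1)
  ws <- grs_weights(g, y, n_boot = 2, seed = 3)
  expect_true(is.na(ws$weights) || abs(ws$weights) < 15)
})

test_that("the weighted score is the genotype-weight product and is linear", {
  expect_equal(weighted_grs(matrix(c(0, 1, 2, 2, 1, 0), 3, 2), c(0, 0)),
               rep(0, 3))
  g1 <- matrix(c(0L, 1L, 2L), 3, 1)
  expect_equal(weighted_grs(g1, log(2)), c(0, log(2), 2 * log(2)))

  withr::with_seed(31, G <- matrix(rbinom(30, 2, 0.3), 10, 3))
  w1 <- c(0.1, -0.5, 0.3); w2 <- c(1, 0.2, 0)
  expect_equal(weighted_grs(G, w1) + weighted_grs(G, w2),
               weighted_grs(G, w1 + w2))
  expect_equal(weighted_grs(G, w1), drop(G %*% w1))
})

test_that("dichotomisation is strict at the empirical percentile", {
  expect_equal(sum(dichotomize_grs(1:100)), 25)
  expect_equal(dichotomize_grs(rep(3.2, 10)), rep(0L, 10))
  # ties at the cutpoint are classified low
  s <- c(1, 2, 3, 3)  # 75th percentile = 3
  expect_equal(dichotomize_grs(s), c(0L, 0L, 0L, 0L))
})

test_that("BH rejection equals the brute-force step-up rule", {
  expect_equal(bh_fdr(c(0.001, 0.9), 0.05), 1L)
  expect_length(bh_fdr(rep(1, 6), 0.05), 0)
  withr::with_seed(33, {
    for (i in 1:200) {
      m <- sample(1:10, 1)
      p <- round(runif(m), 3)
      q <- sample(c(0.01, 0.05, 0.1, 0.25), 1)
      expect_equal(sort(bh_fdr(p, q)), bh_stepup_bruteforce(p, q))
    }
  })
  expect_error(bh_fdr(c(0.1, 1.2), 0.05), "\\[0, 1\\]")
})

test_that("the two-stage screen finds a planted chain and rejects a constant instrument", {
  causal <- cohort_effects(10, 15, causal_snps = 1:4,
                           causal_metabolites = 6)
  co <- generate_cohort(500, 10, 15, causal = causal, seed = 40)
  filt <- filter_metabolites(co$metabolites)
  expect_gt(ncol(filt$data), 10)  # low-CV features survive the QC filter
  w <- grs_weights(co$genotypes, co$outcome, snp_indices = 1:4,
                   n_boot = 20, seed = 41)
  grs <- weighted_grs(co$genotypes, w)
  mr <- two_stage_mr(filt$data, grs, co$age, co$sex, co$outcome)
  planted_col <- match(6, filt$kept)
  expect_true(planted_col %in% mr$passing_set)
  or_row <- mr$stage2[mr$stage2$metabolite == planted_col, ]
  expect_gt(or_row$or, 1)

  expect_error(two_stage_mr(filt$data, rep(1, 500), co$age, co$sex,
                            co$outcome), "constant")
})

test_that("cohorts are reproducible with valid genotypes and recorded truth", {
  co1 <- generate_cohort(120, 6, 8, seed = 50)
  co2 <- generate_cohort(120, 6, 8, seed = 50)
  expect_identical(co1, co2)
  expect_true(all(co1$genotypes %in% 0:2))
  expect_equal(length(co1$outcome), 120)
  expect_error(generate_cohort(50, 3, 3, maf = 0.7), "maf|MAF|\\(0, 0.5\\]")

  # maf = 0.5: mean allele count near 1
  co5 <- generate_cohort(4000, 2, 2, maf = 0.5, seed = 51)
  expect_lt(abs(mean(co5$genotypes) - 1), 0.05)

  # fully null cohort: genotypes carry no outcome information
  cor_gy <- abs(cor(co1$genotypes, co1$outcome))
  expect_lt(max(cor_gy), 0.3)
})
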