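test_that("genotype codings follow the three genetic models", {
  expect_equal(encode_genotype(c(0, 1, 2), "additive"), c(0, 1, 2))
  expect_equal(encode_genotype(c(0, 1, 2), "dominant"), c(0, 1, 1))
  expect_equal(encode_genotype(c(0, 1, 2), "recessive"), c(0, 0, 1))
  expect_true(is.na(encode_genotype(NA, "additive")))
  expect_error(encode_genotype(3, "additive"), "0, 1, 2")
})

test_that("genotype matrix re-orients alleles so the coded allele is minor", {
  calls <- cbind(c(2, 2, 1, 2), c(0, 1, 0, 0))
  snps <- data.frame(id = c("s1", "s2"), chrom = "1", pos = c(1, 2),
                     minor = "G", major = "A", stringsAsFactors = FALSE)
  subj <- data.frame(subject_id = paste0("P", 1:4), sex = "F",
                     stringsAsFactors = FALSE)
  g <- genotype_matrix(calls, snps, subj)
  expect_equal(g$swapped, "s1")
  expect_equal(unname(g$calls[, 1]), c(0L, 0L, 1L, 0L))
  expect_equal(g$snps$minor[1], "A")
  expect_true(all(minor_allele_freq(g) <= 0.5))
})

test_that("noise-free linear construction is recovered exactly", {
  set.seed(1)
  code <- rep(c(0, 1, 2), length.out = 30)
  age <- runif(30, 20, 85)
  y <- 2 * code + 0.004 * age
  f <- snp_regression(y, code, cbind(age = age))
  expect_equal(f$beta, 2, tolerance = 1e-10)
  expect_equal(f$flag, "ok")
})

test_that("snp_regression matches an independent normal-equations oracle", {
  set.seed(2)
  for (i in 1:10) {
    n <- 60
    code <- sample(0:2, n, replace = TRUE)
    covs <- cbind(a = rnorm(n), b = runif(n))
    y <- 0.3 * code + 0.5 * covs[, 1] + rnorm(n)
    f <- snp_regression(y, code, covs)
    o <- ols_oracle(y, cbind(1, code, covs))
    expect_equal(f$beta, o$beta[2], tolerance = 1e-8)
    expect_equal(f$se, unname(o$se[2]), tolerance = 1e-8)
    expect_equal(f$p, unname(o$p[2]), tolerance = 1e-8)
  }
})

test_that("monomorphic and collinear designs are flagged, not fitted", {
  y <- rnorm(20)
  expect_equal(snp_regression(y, rep(1, 20))$flag, "monomorphic")
  code <- sample(0:2, 20, replace = TRUE)
  expect_equal(snp_regression(y, code, cbind(dup = code))$flag, "collinear")
  expect_equal(snp_regression(y[1:3], code[1:3], cbind(a = rnorm(3)))$flag,
               "insufficient_n")
})

test_that("null p-values are approximately uniform", {
  set.seed(3)
  n <- 80
  code <- sample(0:2, n, replace = TRUE, prob = c(0.49, 0.42, 0.09))
  reps <- 1000
  p <- replicate(reps, snp_regression(sample(rnorm(n)), code)$p)
  frac <- mean(p < 0.05)
  # binomial 3.3-sigma band around 0.05
  expect_lt(abs(frac - 0.05), 3.3 * sqrt(0.05 * 0.95 / reps))
  expect_gt(ks.test(p, "punif")$p.value, 0.001)
})

test_that("pooled combined fit equals OLS on the concatenated stages", {
  set.seed(4)
  n <- 90
  ids <- sprintf("I%02d", 1:n)
  code <- setNames(sample(0:2, n, replace = TRUE), ids)
  covs <- matrix(rnorm(n), ncol = 1, dimnames = list(ids, "a"))
  y <- setNames(0.2 * code + 0.1 * covs[, 1] + rnorm(n), ids)
  plan <- stage_plan(ids, sizes = c(30, 30, 30))
  f <- combine_stages(y, code, covs, plan, k = 3)
  o <- ols_oracle(y, cbind(1, code, covs))
  expect_equal(f$beta, o$beta[2], tolerance = 1e-8)
  expect_equal(f$n_used, n)
  # duplicated cohorts: pooled beta equals the single-cohort beta
  ids2 <- c(ids[1:30], paste0("D", ids[1:30]))
  code2 <- setNames(rep(code[1:30], 2), ids2)
  y2 <- setNames(rep(y[1:30], 2), ids2)
  plan2 <- stage_plan(ids2, sizes = c(30, 30))
  f2 <- combine_stages(y2, code2, NULL, plan2, k = 2)
  f1 <- snp_regression(y[1:30], code[1:30])
  expect_equal(f2$beta, f1$beta, tolerance = 1e-10)
})

test_that("a single-stage plan reduces the scan to simple p thresholding", {
  set.seed(6)
  spec <- cohort_spec(n_subjects = 80, n_snps = 40, seed = 99)
  geno <- gen_genotypes(spec)
  ids <- geno$subjects$subject_id
  y <- setNames(rnorm(80), ids)
  plan <- stage_plan(ids, sizes = 80)
  res <- staged_gwas(geno, y, NULL, plan, "additive")
  direct <- vapply(seq_len(40), function(j)
    snp_regression(y, encode_genotype(geno$calls[, j], "additive"))$p,
    numeric(1))
  expect_equal(res$stage1_p, direct, tolerance = 1e-12)
  expect_equal(res$survived_stage == 1,
               !is.na(direct) & direct < 0.05)
})

test_that("the staged filter never admits a SNP any single stage rejects", {
  set.seed(7)
  spec <- cohort_spec(n_subjects = 150, n_snps = 60, seed = 42,
                      causal_snps = data.frame(snp_index = 1:3, beta = 0.4))
  geno <- gen_genotypes(spec)
  covars <- gen_covariates(spec)
  lat <- gen_latent_mec(geno, covars, spec)
  y <- setNames(log1p(lat$latent_mec), lat$subject_id)
  plan <- stage_plan(lat$subject_id, sizes = c(50, 50, 50))
  res <- staged_gwas(geno, y, covars, plan, "additive")
  surv <- res$survived_stage == 3
  for (s in 1:3)
    expect_true(all(res[[sprintf("stage%d_p", s)]][surv] < plan$alpha))
  expect_true(all(res$combined3_p[surv] < plan$alpha))
})

test_that("male subjects are excluded from X-chromosome fits", {
  g <- toy_geno()  # rsC is on X; P2, P5, P8 are male
  ids <- g$subjects$subject_id
  set.seed(8)
  y <- setNames(rnorm(8), ids)
  plan <- stage_plan(ids, sizes = 8)
  res <- staged_gwas(g, y, NULL, plan, "additive")
  females <- ids[g$subjects$sex != "M"]
  fx <- snp_regression(y[females],
                       encode_genotype(g$calls[match(females, ids), 3], "additive"))
  expect_equal(res$stage1_p[res$snp == "rsC"], fx$p, tolerance = 1e-12)
  fa <- snp_regression(y, encode_genotype(g$calls[, 1], "additive"))
  expect_equal(res$stage1_p[res$snp == "rsA"], fa$p, tolerance = 1e-12)
})

test_that("mean phenotype rises with minor-allele count under a positive effect", {
  set.seed(9)
  spec <- cohort_spec(n_subjects = 400, n_snps = 5, seed = 77,
                      causal_snps = data.frame(snp_index = 2, beta = 0.3),
                      noise_sd = 0.1)
  geno <- gen_genotypes(spec)
  covars <- gen_covariates(spec)
  lat <- gen_latent_mec(geno, covars, spec)
  y <- log1p(lat$latent_mec)
  mg <- tapply(y, geno$calls[, 2], mean)
  expect_true(all(diff(mg[order(as.integer(names(mg)))]) > 0))
})
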