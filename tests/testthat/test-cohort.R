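test_that("generators are pure functions of (spec, seed)", {
  spec <- cohort_spec(n_subjects = 40, n_snps = 15, seed = 123)
  g1 <- gen_genotypes(spec); g2 <- gen_genotypes(spec)
  expect_identical(g1$calls, g2$calls)
  c1 <- gen_covariates(spec); c2 <- gen_covariates(spec)
  expect_identical(c1, c2)
  spec2 <- cohort_spec(n_subjects = 40, n_snps = 15, seed = 124)
  expect_false(identical(gen_genotypes(spec2)$calls, g1$calls))
})

test_that("generated genotypes sit at Hardy-Weinberg proportions", {
  spec <- cohort_spec(n_subjects = 10000, n_snps = 60, seed = 55,
                      maf_range = c(0.3, 0.3))
  g <- gen_genotypes(spec)
  tab <- hwe_table(g)
  # 1-df chi-square exceeds the alpha=0.001 critical value ~ alpha of the time
  expect_gte(mean(tab$p_chi2 > 0.001), 0.99)
  expect_equal(mean(minor_allele_freq(g)), 0.3, tolerance = 0.01)
})

test_that("LD blocks induce the requested within-block correlation", {
  spec <- cohort_spec(n_subjects = 400, n_snps = 12, seed = 66,
                      maf_range = c(0.2, 0.4),
                      ld_blocks = list(list(size = 5, rho = 0.95)))
  g <- gen_genotypes(spec)
  r2in <- ld_r2_matrix(g, g$snps$id[1:5])
  expect_gt(median(r2in[upper.tri(r2in)], na.rm = TRUE), 0.8)
  # SNPs outside the block stay uncorrelated with it
  r_out <- ld_em(g$calls[, 1], g$calls[, 9])
  expect_lt(r_out$r2, 0.2)
})

test_that("covariates respect their configured ranges", {
  spec <- cohort_spec(n_subjects = 500, n_snps = 5, seed = 77)
  cv <- gen_covariates(spec)
  expect_true(all(cv$age_years >= 20 & cv$age_years <= 85))
  expect_true(all(cv$remi_rate_ug_kg_min > 0))
  expect_true(all(cv$endsurg_fentanyl_ug >= 100))
  expect_true(all(cv$pain2h_score %in% 0:10))
})

test_that("latent MEC decomposes additively on the log scale", {
  spec <- cohort_spec(n_subjects = 200, n_snps = 10, seed = 88,
                      maf_range = c(0.3, 0.4),
                      causal_snps = data.frame(snp_index = 4, beta = 0.2),
                      noise_sd = 0)
  g <- gen_genotypes(spec)
  cv <- gen_covariates(spec)
  lat <- gen_latent_mec(g, cv, spec)
  expect_true(all(lat$latent_mec > 0))
  expect_equal(log(lat$latent_mec),
               attr(lat, "intercept") + lat$lp_genetic + lat$lp_covariate +
                 lat$lp_residual, tolerance = 1e-12)
  # per-copy effect appears exactly between genotype groups at zero noise
  resid <- log(lat$latent_mec) - lat$lp_covariate
  mg <- tapply(resid, g$calls[, 4], mean)
  expect_equal(as.vector(diff(mg)), c(0.2, 0.2), tolerance = 1e-10)
})

test_that("no causal SNPs and no noise gives a covariate-only phenotype", {
  spec <- cohort_spec(n_subjects = 50, n_snps = 5, seed = 99, noise_sd = 0,
                      covariate_effects = c(age = 0, remi_rate = 0,
                                            endsurg_fentanyl = 0, pain2h = 0))
  g <- gen_genotypes(spec)
  cv <- gen_covariates(spec)
  lat <- gen_latent_mec(g, cv, spec)
  expect_true(all(abs(lat$latent_mec - exp(spec$intercept)) < 1e-12))
})

test_that("log latent variance decomposes into its components", {
  spec <- cohort_spec(n_subjects = 50000, n_snps = 4, seed = 101,
                      maf_range = c(0.3, 0.3),
                      causal_snps = data.frame(snp_index = 1, beta = 0.25),
                      noise_sd = 0.3)
  g <- gen_genotypes(spec)
  cv <- gen_covariates(spec)
  lat <- gen_latent_mec(g, cv, spec)
  v_tot <- var(log(lat$latent_mec))
  v_sum <- var(lat$lp_genetic) + var(lat$lp_covariate) + var(lat$lp_residual)
  # components are independent by construction
  expect_equal(v_tot, v_sum, tolerance = 0.03)
  expect_equal(var(lat$lp_genetic), 0.25^2 * 2 * 0.3 * 0.7, tolerance = 0.03)
})

test_that("closed-loop dosing honours the pump program", {
  spec <- cohort_spec(n_subjects = 1, n_snps = 1, seed = 7)
  p <- pk_fent()
  for (M in c(0.5, 1.0, 1.8)) {
    hst <- gen_dosing(M, p, spec, "sub")
    dem <- hst$events$time_min[hst$events$kind == "pca_demand"]
    if (length(dem) > 1) expect_gte(min(diff(dem)), 5 - 1e-9)
    # rolling-hour cap
    for (t in dem) expect_lte(sum(dem > t - 60 & dem <= t), 12)
    expect_lte(20 * length(dem), 1000 + 1e-9)
  }
})

test_that("the pump cap binds when the threshold forces rapid demands", {
  # high MEC relative to the demand dose: lockout-limited pressing
  spec <- cohort_spec(n_subjects = 1, n_snps = 1, seed = 7,
                      initial_bolus_ug = 300,
                      pca_settings = list(demand_dose_ug = 20, lockout_min = 5,
                                          max_per_hour = 6, capacity_ug = 400))
  p <- pk_fent()
  hst <- gen_dosing(4, p, spec, "sub")
  dem <- hst$events$time_min[hst$events$kind == "pca_demand"]
  expect_gt(length(dem), 6)
  for (t in dem) expect_lte(sum(dem > t - 60 & dem <= t), 6)
  expect_true(any(!attr(hst, "unconstrained")))
})

test_that("an unreachable threshold yields a flagged bolus-only history", {
  spec <- cohort_spec(n_subjects = 1, n_snps = 1, seed = 7)
  hst <- gen_dosing(50, pk_fent(), spec, "sub")
  expect_true(attr(hst, "unreachable"))
  expect_equal(nrow(hst$events), 1)
  expect_equal(hst$events$kind, "initial_bolus")
})

test_that("extracted window means recover the latent MEC without behaviour noise", {
  spec <- cohort_spec(n_subjects = 30, n_snps = 10, seed = 11,
                      behavior_noise_sd = 0)
  co <- gen_cohort(spec)
  p <- pk_fent()
  for (i in seq_len(10)) {
    fl <- co$truth$dosing_flags[i, ]
    if (fl$unreachable || fl$n_unconstrained < 3) next
    rec <- extract_mec(co$histories[[i]], p)
    m <- rec$window_means$effect[rec$window_means$window_h == 24]
    expect_lt(abs(m - co$latent$latent_mec[i]) / co$latent$latent_mec[i], 0.02)
  }
})

test_that("the truth record lists exactly the configured causal SNPs", {
  spec <- cohort_spec(n_subjects = 30, n_snps = 20, seed = 12,
                      causal_snps = data.frame(snp_index = c(3, 17),
                                               beta = c(0.2, -0.1)))
  co <- gen_cohort(spec, dosing = FALSE)
  expect_equal(co$truth$causal_ids, c("snp0003", "snp0017"))
  expect_equal(co$truth$causal_snps$beta, c(0.2, -0.1))
})
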