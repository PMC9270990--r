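test_that("identical config and seed reproduce the cohort bit for bit", {
  cfg <- sim_config(n_subjects = 300, n_genes = 12, seed = 88,
                    causal_genes = c(GENE0005 = 0.4))
  a <- suppressWarnings(simulate_cohort(cfg))
  b <- suppressWarnings(simulate_cohort(cfg))
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$variants, b$variants)
  expect_identical(a$true_scores, b$true_scores)
  d <- simulate_cohort(sim_config(n_subjects = 300, n_genes = 12, seed = 89))
  expect_false(identical(a$genotypes, d$genotypes))
})

test_that("configuration errors are caught", {
  expect_error(sim_config(n_subjects = 0), "n_subjects")
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(category_mixture = c(missense_variant = 0.5)),
               "sum to 1")
  expect_error(sim_config(category_mixture = c(banana_variant = 1)),
               "unknown consequence")
  expect_error(
    simulate_cohort(sim_config(n_genes = 5,
                               causal_genes = c(NOPE = 1))),
    "causal gene")
})

test_that("simulated frequencies and structure match the configuration", {
  cfg <- sim_config(n_subjects = 50000, n_genes = 2, variants_per_gene = 1,
                    maf_distribution = list(fixed = 0.005),
                    n_subpopulations = 1, subpop_frequency_divergence = 0,
                    missing_rate = 0, x_gene_fraction = 0, seed = 3)
  sim <- simulate_cohort(cfg)
  # marginal allele frequency within 3 standard errors of the target
  se <- sqrt(0.005 * 0.995 / (2 * 50000))
  f <- colMeans(sim$genotypes) / 2
  expect_true(all(abs(f - 0.005) < 3 * se))

  cfg2 <- sim_config(n_subjects = 400, n_genes = 40, seed = 4,
                     x_gene_fraction = 0.5, missing_rate = 0.1)
  sim2 <- simulate_cohort(cfg2)
  # per-population MAFs capped at the rare-variant limit
  expect_true(all(attr(sim2$variants, "pop_maf") <= 0.01))
  expect_true(all(sim2$variants$maf_true <= 0.01))
  # males are hemizygous on X
  xv <- sim2$variants$chrom == "X"
  expect_true(any(xv))
  male <- sim2$cohort$sex == 1
  expect_true(all(sim2$genotypes[male, xv] <= 1L, na.rm = TRUE))
  # missingness close to its configured rate
  expect_lt(abs(mean(is.na(sim2$genotypes)) - 0.1), 0.01)
})

test_that("a strong planted effect makes its gene the top mean SLP", {
  set.seed(61)
  n_rep <- 100
  slps <- matrix(NA_real_, n_rep, 8)
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n_subjects = 1200, n_genes = 8, seed = 6000 + r,
                      causal_genes = c(GENE0003 = 1.2))
    sim <- suppressWarnings(simulate_cohort(cfg))
    covar <- sim_covariates(sim)
    qc <- qc_variants(sim$genotypes, sim$cohort$case,
                      is_x = sim$variants$chrom == "X",
                      is_male = sim$cohort$sex == 1)
    qual <- sim$variants[qc$pass, ]
    qual$is_x <- qual$chrom == "X"
    g <- sim$genotypes[, qc$pass, drop = FALSE]
    maf <- variant_maf(g, qual$is_x, sim$cohort$sex == 1)
    qual <- weight_variants(qual, pmin(maf, 0.01))
    sc <- gene_burden_scores(g, qual, is_male = sim$cohort$sex == 1)
    scan <- burden_scan(sc, sim$cohort$case, covar)
    slps[r, match(scan$gene, paste0("GENE000", 1:8))] <- scan$slp
  }
  mean_slp <- colMeans(slps, na.rm = TRUE)
  expect_gt(mean_slp[3], 0)
  expect_equal(which.max(abs(mean_slp)), 3L)
})

test_that("null cohorts give uniform gene-wise P values in the dense regime", {
  cfg <- sim_config(n_subjects = 4000, n_genes = 400, variants_per_gene = 12,
                    maf_distribution = list(fixed = 0.008), seed = 5)
  sim <- simulate_cohort(cfg)
  run <- run_pipeline(sim$genotypes, sim$variants, sim$cohort, "case",
                      qq_exclude = 20)
  res <- run$results$case$gene_results
  frac <- mean(res$p < 0.05)
  # 0.05 within 3-sigma Monte-Carlo error at 400 genes
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / nrow(res)))
})

test_that("ancestry confounding inflates the scan unless PCs are included", {
  cfg <- sim_config(n_subjects = 3000, n_genes = 500, seed = 21,
                    subpop_frequency_divergence = 0.1,
                    covariate_effects = list(sex = 0.2, pc = c(1, rep(0, 19))))
  sim <- simulate_cohort(cfg)
  run <- run_pipeline(sim$genotypes, sim$variants, sim$cohort, "case",
                      qq_exclude = 25)
  r <- run$results$case
  g <- sim$genotypes[, r$qc$id[r$qc$pass], drop = FALSE]
  sc <- gene_burden_scores(g, r$variants, is_male = sim$cohort$sex == 1)
  no_pc <- burden_scan(sc, sim$cohort$case, cbind(sex = sim$cohort$sex))
  q_no <- qq_summary(no_pc$slp[is.na(no_pc$note)], n_exclude = 25)
  grad_pc <- r$qq$branches$gradient
  grad_no <- q_no$branches$gradient
  # without adjustment both branches blow up well past the adjusted scan
  expect_true(all(grad_no > 1.3))
  expect_true(all(grad_no > grad_pc + 0.2))
  expect_gt(mean(no_pc$chisq) / mean(r$gene_results$chisq), 1.5)
})
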