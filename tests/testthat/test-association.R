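# simple logistic cohort fixture for association-level tests
logit_cohort <- function(n, beta, maf = 0.1, intercept = -1.5, n_cov = 3) {
  cov <- matrix(rnorm(n * n_cov), n, n_cov,
                dimnames = list(NULL, paste0("c", seq_len(n_cov))))
  s <- rbinom(n, 2, maf)
  eta <- intercept + 0.3 * cov[, 1] + beta * s
  list(score = s, cov = cov, status = rbinom(n, 1, plogis(eta)))
}

test_that("gene LRT matches the stats::glm likelihood-ratio oracle", {
  set.seed(11)
  d <- logit_cohort(800, beta = 0.6)
  res <- gene_lrt(d$score, d$status, d$cov)
  f0 <- glm(d$status ~ d$cov, family = binomial)
  f1 <- glm(d$status ~ d$score + d$cov, family = binomial)
  lrt <- anova(f0, f1, test = "LRT")
  expect_equal(res$chisq, lrt$Deviance[2], tolerance = 1e-6)
  expect_equal(res$p, lrt$`Pr(>Chi)`[2], tolerance = 1e-6)
  expect_equal(res$beta, unname(coef(f1)["d$score"]), tolerance = 1e-6)
  expect_equal(res$se,
               unname(summary(f1)$coefficients["d$score", "Std. Error"]),
               tolerance = 1e-5)
  expect_equal(abs(res$slp), -log10(res$p))
  expect_gt(res$slp, 0)  # risk-increasing score: SLP signed positive
})

test_that("constant scores and protective effects are handled", {
  set.seed(12)
  d <- logit_cohort(800, beta = -0.8)
  res <- gene_lrt(d$score, d$status, d$cov)
  expect_lt(res$slp, 0)
  cst <- gene_lrt(rep(2, 800), d$status, d$cov)
  expect_equal(cst$chisq, 0)
  expect_equal(cst$p, 1)
  expect_equal(cst$slp, 0)
  expect_equal(cst$note, "constant_score")
})

test_that("Wald and LRT P values agree within a factor of two for moderate effects", {
  set.seed(13)
  for (rep in 1:5) {
    d <- logit_cohort(4000, beta = 0.3)
    res <- gene_lrt(d$score, d$status, d$cov)
    p_wald <- 2 * pnorm(abs(res$beta / res$se), lower.tail = FALSE)
    expect_gt(p_wald / res$p, 0.5)
    expect_lt(p_wald / res$p, 2)
  }
})

test_that("burden_scan reproduces per-gene gene_lrt results", {
  set.seed(14)
  d <- logit_cohort(500, beta = 0.5)
  scores <- cbind(g1 = d$score, g2 = rnorm(500), g3 = rep(1, 500))
  scan <- burden_scan(scores, d$status, d$cov)
  for (g in colnames(scores)) {
    one <- gene_lrt(scores[, g], d$status, d$cov)
    expect_equal(scan$slp[scan$gene == g], one$slp, tolerance = 1e-10)
    expect_equal(scan$chisq[scan$gene == g], one$chisq, tolerance = 1e-10)
  }
  expect_equal(scan$note[scan$gene == "g3"], "constant_score")
})

test_that("variant tests flag monomorphic and collinear variants and recover direction", {
  set.seed(15)
  d <- logit_cohort(1500, beta = -0.7)
  counts <- cbind(v1 = d$score, v2 = rep(0, 1500), v3 = d$score)
  res <- variant_test(counts, d$status, d$cov)
  expect_equal(res$note[res$id == "v2"], "monomorphic")
  expect_true("collinear" %in% res$note)  # duplicated covariate dropped
  est <- res[res$id == "v1", ]
  expect_lt(est$or, 1)
  # protective variant: mean fitted OR < 1 over replicates
  ors <- replicate(50, {
    d <- logit_cohort(600, beta = -0.7)
    variant_test(cbind(v = d$score), d$status, d$cov)$or
  })
  expect_lt(mean(log(ors)), 0)
  # allele frequencies computed per group among genotyped subjects
  cnt <- cbind(v = c(1, 1, 0, 0))
  st <- c(1, 0, 1, 0)
  out <- variant_test(cnt, st, covariates = NULL)
  expect_equal(out$freq_case, 0.25)
  expect_equal(out$freq_control, 0.25)
})

test_that("category decomposition switches to Fisher's exact below 50 occurrences", {
  set.seed(16)
  n <- 4000
  # one category with exactly 49 carrier alleles, one with 120
  g <- cbind(rare = geno_col(n - 49, 49, 0), common = geno_col(n - 120, 120, 0))
  g <- g[sample(n), ]
  v <- data.frame(id = c("rare", "common"),
                  category = c("Disruptive", "Protein altering"))
  status <- rbinom(n, 1, 0.2)
  cov <- matrix(rnorm(n * 2), n, 2)
  res <- category_decomposition(g, v, status, cov)
  expect_equal(res$test[res$category == "Disruptive"], "fisher_exact")
  expect_equal(res$occurrences[res$category == "Disruptive"], 49)
  expect_equal(res$test[res$category == "Protein altering"], "wald")
  expect_true(all(is.finite(res$p)))
  # boundary: exactly 50 occurrences uses the Wald test
  g50 <- cbind(rare = geno_col(n - 50, 50, 0))
  v50 <- data.frame(id = "rare", category = "Disruptive")
  expect_equal(category_decomposition(g50, v50, status, cov)$test, "wald")
  # Unused categories and empty categories are left out
  v2 <- data.frame(id = c("rare", "common"),
                   category = c("Unused", "Protein altering"))
  res2 <- category_decomposition(g, v2, status, cov)
  expect_equal(res2$category, "Protein altering")
})

test_that("Bonferroni SLP threshold follows the closed form", {
  expect_equal(bonferroni_slp_threshold(1, 1), -log10(0.05))
  expect_equal(bonferroni_slp_threshold(1000, 1), 4.301, tolerance = 5e-4)
  expect_equal(bonferroni_slp_threshold(100, 2, 0.01),
               -log10(0.01 / 200))
  expect_error(bonferroni_slp_threshold(0, 1), "n_genes")
})
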