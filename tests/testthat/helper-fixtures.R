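# Shared fixtures and independent brute-force oracles.

# genotype column from explicit class counts (0/1/2/NA)
geno_col <- function(n0, n1, n2, nmiss = 0) {
  c(rep(0L, n0), rep(1L, n1), rep(2L, n2), rep(NA_integer_, nmiss))
}

# random small genotype matrix with missingness
random_geno <- function(n, nv, maf_max = 0.2, miss = 0.05) {
  g <- matrix(stats::rbinom(n * nv, 2, stats::runif(nv, 0.01, maf_max)[
    rep(seq_len(nv), each = n)]), n, nv)
  g[stats::runif(n * nv) < miss] <- NA_integer_
  storage.mode(g) <- "integer"
  colnames(g) <- paste0("v", seq_len(nv))
  rownames(g) <- paste0("s", seq_len(n))
  g
}

# brute-force gene score oracle: explicit per-subject, per-variant loops
brute_scores <- function(geno, variants, is_male = NULL) {
  n <- nrow(geno)
  if (is.null(is_male)) is_male <- rep(FALSE, n)
  vx <- if ("is_x" %in% names(variants)) variants$is_x else
    rep(FALSE, nrow(variants))
  genes <- unique(variants$gene)
  out <- matrix(0, n, length(genes), dimnames = list(rownames(geno), genes))
  for (gi in seq_along(genes)) {
    rows <- which(variants$gene == genes[gi])
    for (r in rows) {
      j <- which(colnames(geno) == variants$id[r])
      cnt <- numeric(n)
      for (i in seq_len(n)) {
        gg <- geno[i, j]
        cnt[i] <- if (is.na(gg)) NA else if (vx[r] && is_male[i]) 2 * gg else gg
      }
      mu <- mean(cnt, na.rm = TRUE)
      cnt[is.na(cnt)] <- mu
      out[, gi] <- out[, gi] + variants$weight[r] * cnt
    }
  }
  out
}

# brute-force QC oracle: recount genotype classes and frequencies per group
brute_qc_pass <- function(geno, status, is_x = NULL, is_male = NULL,
                          maf_cap = 0.01, miss_cap = 0.10) {
  n <- nrow(geno)
  if (is.null(is_x)) is_x <- rep(FALSE, ncol(geno))
  if (is.null(is_male)) is_male <- rep(FALSE, n)
  status <- as.logical(status)
  vapply(seq_len(ncol(geno)), function(j) {
    for (grp in list(which(status), which(!status))) {
      g <- geno[grp, j]
      male <- is_male[grp]
      miss <- mean(is.na(g))
      if (miss > miss_cap) return(FALSE)
      het <- hom_ref <- hom_alt <- 0
      alt <- tot <- 0
      for (i in seq_along(g)) {
        if (is.na(g[i])) next
        hemi <- is_x[j] && male[i]
        if (hemi) {
          if (g[i] == 0) hom_ref <- hom_ref + 1 else hom_alt <- hom_alt + 1
          alt <- alt + g[i]; tot <- tot + 1
        } else {
          if (g[i] == 0) hom_ref <- hom_ref + 1
          if (g[i] == 1) het <- het + 1
          if (g[i] == 2) hom_alt <- hom_alt + 1
          alt <- alt + g[i]; tot <- tot + 2
        }
      }
      f <- alt / tot
      if (min(f, 1 - f) > maf_cap) return(FALSE)
      if (het < hom_ref && het < hom_alt) return(FALSE)
    }
    TRUE
  }, logical(1))
}

# covariate matrix from a simulated cohort
sim_covariates <- function(sim) {
  pcs <- grep("^PC", names(sim$cohort), value = TRUE)
  as.matrix(cbind(sex = sim$cohort$sex, sim$cohort[pcs]))
}
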