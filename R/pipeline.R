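# End-to-end orchestration: QC -> weighting -> scoring -> gene-wise LRTs ->
# gene sets -> QQ diagnostics, with TSV outputs and a run manifest.

#' Run the full weighted burden analysis
#'
#' For each requested phenotype: restricts to subjects with a non-missing
#' status and complete covariates, applies variant QC ([qc_variants()]),
#' weights qualifying variants by pooled MAF and functional annotation
#' ([weight_variants()]), computes gene-wise burden scores
#' ([gene_burden_scores()]), tests every gene by likelihood-ratio test
#' ([burden_scan()]), optionally aggregates gene sets ([set_scan()]) and
#' summarizes calibration ([qq_summary()]). When `out_dir` is given, each
#' stage writes a commented TSV and a run manifest (DCF key-value file)
#' records configuration and stage counts.
#'
#' @param genotypes Subjects x variants integer matrix (or path to a
#'   genotype TSV / VCF written by [write_cohort()]).
#' @param variants Data.frame with columns `id`, `gene`, `chrom`,
#'   `consequence` and optionally `polyphen`, `sift` (or path to an
#'   annotation TSV).
#' @param cohort Data.frame with columns `subject`, `sex` (male = 1), the
#'   PC covariates `PC1`... and one status column (1/0/NA) per phenotype
#'   (or path to a TSV combining covariates and phenotype columns).
#' @param phenotypes Character vector of status column names in `cohort`.
#' @param gene_sets Optional named list of gene sets or path to a GMT file.
#' @param weight_table Weight table (see [annotation_weights()]).
#' @param n_pcs Number of PC covariates to include (default 20).
#' @param alpha Family-wise error rate for Bonferroni thresholds.
#' @param maf_cap,miss_cap QC caps (see [qc_variants()]).
#' @param fisher_threshold Category-decomposition Fisher cutoff, echoed in
#'   the manifest for downstream use.
#' @param qq_exclude Extremes excluded per tail in the QQ summary; the
#'   summary is skipped when too few genes are scored.
#' @param out_dir Optional output directory.
#' @return List of class `wb_run`: per-phenotype results (`qc`,
#'   `variants` (weighted qualifying variants), `gene_results`,
#'   `set_results`, `qq`, `n_subjects`, `slp_threshold`) plus `manifest`.
#' @export
run_pipeline <- function(genotypes, variants, cohort, phenotypes,
                         gene_sets = NULL,
                         weight_table = annotation_weights(),
                         n_pcs = 20, alpha = 0.05, maf_cap = 0.01,
                         miss_cap = 0.10, fisher_threshold = 50,
                         qq_exclude = 100, out_dir = NULL) {
  if (is.character(genotypes)) {
    genotypes <- if (grepl("\\.vcf$", genotypes)) {
      read_genotypes_vcf(genotypes)$genotypes
    } else {
      read_genotypes_tsv(genotypes)
    }
  }
  if (is.character(variants)) variants <- read_wb_tsv(variants)
  if (is.character(cohort)) cohort <- read_wb_tsv(cohort)
  if (is.character(gene_sets)) gene_sets <- read_gmt(gene_sets)
  stopifnot(is.matrix(genotypes),
            all(c("id", "gene", "chrom", "consequence") %in% names(variants)),
            all(c("subject", "sex") %in% names(cohort)),
            all(phenotypes %in% names(cohort)))
  pc_cols <- paste0("PC", seq_len(n_pcs))
  if (!all(pc_cols %in% names(cohort))) {
    stop("cohort table lacks covariate column(s): ",
         paste(setdiff(pc_cols, names(cohort)), collapse = ", "))
  }
  row_match <- match(cohort$subject, rownames(genotypes))
  if (any(is.na(row_match))) {
    stop("subject(s) in cohort table absent from genotype matrix")
  }
  col_match <- match(variants$id, colnames(genotypes))
  if (any(is.na(col_match))) {
    stop("variant id(s) in annotation table absent from genotype matrix")
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }

  is_x_all <- variants$chrom %in% c("X", "chrX", "23")
  results <- list()
  manifest <- list(n_subjects_genotyped = nrow(genotypes),
                   n_variants_input = nrow(variants),
                   n_pcs = n_pcs, alpha = alpha, maf_cap = maf_cap,
                   miss_cap = miss_cap,
                   fisher_threshold = fisher_threshold,
                   qq_exclude = qq_exclude,
                   phenotypes = paste(phenotypes, collapse = ","))

  for (ph in phenotypes) {
    status_all <- cohort[[ph]]
    covar_all <- as.matrix(cbind(sex = cohort$sex, cohort[pc_cols]))
    keep <- !is.na(status_all) & stats::complete.cases(covar_all)
    status <- as.numeric(status_all[keep])
    covar <- covar_all[keep, , drop = FALSE]
    g <- genotypes[row_match[keep], col_match, drop = FALSE]
    colnames(g) <- variants$id
    is_male <- cohort$sex[keep] == 1

    # only segregating sites are observable variants in this cohort
    seg <- colSums(g, na.rm = TRUE) > 0
    vars_ph <- variants[seg, , drop = FALSE]
    is_x <- is_x_all[seg]
    g <- g[, seg, drop = FALSE]

    qc <- qc_variants(g, status, is_x = is_x, is_male = is_male,
                      maf_cap = maf_cap, miss_cap = miss_cap)
    pass <- qc$pass
    qual <- vars_ph[pass, , drop = FALSE]
    qual$is_x <- is_x[pass]
    gq <- g[, pass, drop = FALSE]
    maf <- variant_maf(gq, is_x = qual$is_x, is_male = is_male)
    qual <- weight_variants(qual, pmin(maf, maf_cap), table = weight_table)
    qual$maf <- maf

    scores <- gene_burden_scores(gq, qual, is_male = is_male)
    res <- burden_scan(scores, status, covar)
    res <- res[order(-res$slp), , drop = FALSE]
    slp_thr <- bonferroni_slp_threshold(nrow(res), length(phenotypes),
                                        alpha)

    set_res <- NULL
    if (!is.null(gene_sets)) {
      set_res <- set_scan(res, gene_sets, n_phenotypes = length(phenotypes),
                          alpha = alpha)
    }
    # calibration is a property of performed tests: genes flagged as
    # untestable (constant score, collinearity, non-convergence) carry a
    # placeholder SLP of 0, not a test statistic, and are left out
    tested <- res$slp[is.na(res$note)]
    qq <- NULL
    if (length(tested) >= 2 * qq_exclude + 2) {
      qq <- qq_summary(tested, n_exclude = qq_exclude)
    }

    results[[ph]] <- list(qc = qc, variants = qual, gene_results = res,
                          set_results = set_res, qq = qq,
                          n_subjects = sum(keep),
                          n_cases = sum(status == 1),
                          slp_threshold = slp_thr)
    manifest[[paste0(ph, "_n_subjects")]] <- sum(keep)
    manifest[[paste0(ph, "_n_segregating_variants")]] <- sum(seg)
    manifest[[paste0(ph, "_n_cases")]] <- sum(status == 1)
    manifest[[paste0(ph, "_n_qualifying_variants")]] <- sum(pass)
    manifest[[paste0(ph, "_n_genes")]] <- nrow(res)
    manifest[[paste0(ph, "_slp_threshold")]] <- round(slp_thr, 4)

    if (!is.null(out_dir)) {
      note <- paste("phenotype:", ph)
      write_wb_tsv(qc, file.path(out_dir, paste0(ph, "_qc_report.tsv")),
                   comments = note)
      out_res <- res
      out_res$p <- signif(out_res$p, 6)
      out_res$slp <- round(out_res$slp, 4)
      write_wb_tsv(out_res,
                   file.path(out_dir, paste0(ph, "_gene_results.tsv")),
                   comments = c(note, paste("slp_threshold:",
                                            round(slp_thr, 4))))
      if (!is.null(set_res)) {
        write_wb_tsv(set_res,
                     file.path(out_dir, paste0(ph, "_set_results.tsv")),
                     comments = c(note,
                                  paste("threshold:",
                                        signif(attr(set_res, "threshold"),
                                               4))))
      }
      if (!is.null(qq)) {
        write_wb_tsv(qq$branches,
                     file.path(out_dir, paste0(ph, "_qq_summary.tsv")),
                     comments = note)
      }
    }
  }

  if (!is.null(out_dir)) {
    write.dcf(as.data.frame(manifest, check.names = FALSE),
              file.path(out_dir, "manifest.dcf"))
  }
  structure(list(results = results, manifest = manifest), class = "wb_run")
}

#' @export
print.wb_run <- function(x, ...) {
  cat("Weighted burden analysis run\n")
  for (ph in names(x$results)) {
    r <- x$results[[ph]]
    cat(sprintf("  %s: %d subjects (%d cases), %d genes, |SLP| threshold %.2f\n",
                ph, r$n_subjects, r$n_cases, nrow(r$gene_results),
                r$slp_threshold))
    top <- r$gene_results[which.max(abs(r$gene_results$slp)), ]
    cat(sprintf("    top gene %s: SLP %.2f\n", top$gene, top$slp))
  }
  invisible(x)
}
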