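# Variant QC, missing-genotype imputation, X-hemizygote handling and
# gene-wise weighted burden scores.
#
# Genotype matrices are subjects x variants integer matrices of alternate
# allele counts with NA for missing calls. Males on X-chromosome variants
# are stored hemizygous (0/1) and doubled to 0/2 wherever alleles are
# counted, so that a hemizygous carrier scores like a homozygote.

.check_geno <- function(genotypes, is_x, is_male) {
  stopifnot(is.matrix(genotypes))
  nv <- ncol(genotypes)
  if (is.null(is_x)) is_x <- rep(FALSE, nv)
  if (is.null(is_male)) is_male <- rep(FALSE, nrow(genotypes))
  stopifnot(length(is_x) == nv, length(is_male) == nrow(genotypes))
  if (any(is_x) && any(is_male)) {
    gx <- genotypes[is_male, is_x, drop = FALSE]
    if (any(gx == 2L, na.rm = TRUE)) {
      stop("inconsistent ploidy: male X-chromosome genotypes must be ",
           "hemizygous (0 or 1)")
    }
  }
  list(is_x = as.logical(is_x), is_male = as.logical(is_male))
}

#' Allele counts with X-chromosome hemizygote doubling
#'
#' Converts raw genotypes to the allele counts used in burden scores and
#' single-variant models: autosomal counts are the diploid 0/1/2 calls,
#' while hemizygous males on the X chromosome are treated as homozygotes
#' (a carried allele counts as 2). Missing calls stay `NA`.
#'
#' @param genotypes Integer matrix, subjects x variants, of alternate
#'   allele counts (`NA` = missing); male X entries must be 0/1.
#' @param is_x Logical per variant, `TRUE` for X-chromosome variants
#'   (`NULL` = all autosomal).
#' @param is_male Logical per subject (`NULL` = all female/diploid).
#' @return Numeric matrix of allele counts, same shape as `genotypes`.
#' @export
allele_counts <- function(genotypes, is_x = NULL, is_male = NULL) {
  fl <- .check_geno(genotypes, is_x, is_male)
  counts <- genotypes * 1.0
  if (any(fl$is_x) && any(fl$is_male)) {
    counts[fl$is_male, fl$is_x] <- 2 * counts[fl$is_male, fl$is_x]
  }
  counts
}

#' Pooled minor allele frequency per variant
#'
#' Frequency of the minor allele among called genotypes, counting two
#' alleles per diploid call and one per hemizygous male X call.
#'
#' @inheritParams allele_counts
#' @return Numeric vector of MAFs (length `ncol(genotypes)`); `NA` when a
#'   variant has no called genotypes.
#' @export
variant_maf <- function(genotypes, is_x = NULL, is_male = NULL) {
  fl <- .check_geno(genotypes, is_x, is_male)
  called <- !is.na(genotypes)
  alt <- colSums(genotypes, na.rm = TRUE)
  total <- 2 * colSums(called)
  if (any(fl$is_x) && any(fl$is_male)) {
    # males contribute a single X allele
    male_called <- colSums(called[fl$is_male, fl$is_x, drop = FALSE])
    total[fl$is_x] <- total[fl$is_x] - male_called
  }
  f <- ifelse(total > 0, alt / total, NA_real_)
  pmin(f, 1 - f)
}

.class_counts <- function(genotypes, is_x, is_male) {
  # het / hom counts with male X hemizygotes counted as homozygotes
  n0 <- colSums(genotypes == 0L, na.rm = TRUE)
  n1 <- colSums(genotypes == 1L, na.rm = TRUE)
  n2 <- colSums(genotypes == 2L, na.rm = TRUE)
  if (any(is_x) && any(is_male)) {
    m1 <- colSums(genotypes[is_male, is_x, drop = FALSE] == 1L, na.rm = TRUE)
    n1[is_x] <- n1[is_x] - m1
    n2[is_x] <- n2[is_x] + m1
  }
  list(hom_ref = n0, het = n1, hom_alt = n2)
}

#' Variant quality-control filter
#'
#' Applies the three exclusion rules for qualifying variants, each
#' evaluated separately in cases and in controls: (i) minor allele
#' frequency above `maf_cap` (default 0.01) in either group; (ii) more than
#' `miss_cap` (default 10%) of genotypes missing in either group; (iii) a
#' heterozygote count smaller than both homozygote counts in either group
#' (a genotyping-artefact signature for a rare variant). When several rules
#' fail, the recorded reason follows that order. Group MAFs use called
#' genotypes only.
#'
#' @inheritParams allele_counts
#' @param status Case indicator per subject (logical or 0/1); both groups
#'   must be non-empty.
#' @param maf_cap Maximum per-group MAF for a qualifying variant.
#' @param miss_cap Maximum per-group missing-genotype fraction.
#' @return Data.frame, one row per variant: `id`, per-group missing
#'   fractions, het/hom counts and MAFs, `pass` flag and failure `reason`
#'   (`NA` when passing; otherwise `maf_gt_threshold`, `missingness` or
#'   `het_lt_homs`).
#' @export
qc_variants <- function(genotypes, status, is_x = NULL, is_male = NULL,
                        maf_cap = 0.01, miss_cap = 0.10) {
  fl <- .check_geno(genotypes, is_x, is_male)
  status <- as.logical(status)
  if (any(is.na(status))) stop("status must not contain NA")
  if (!any(status) || !any(!status)) {
    stop("both cases and controls must be present")
  }
  per_group <- function(rows) {
    g <- genotypes[rows, , drop = FALSE]
    cc <- .class_counts(g, fl$is_x, fl$is_male[rows])
    list(miss = colMeans(is.na(g)),
         maf = variant_maf(g, fl$is_x, fl$is_male[rows]),
         hom_ref = cc$hom_ref, het = cc$het, hom_alt = cc$hom_alt)
  }
  ca <- per_group(status)
  co <- per_group(!status)

  fail_maf <- (!is.na(ca$maf) & ca$maf > maf_cap) |
    (!is.na(co$maf) & co$maf > maf_cap)
  fail_miss <- ca$miss > miss_cap | co$miss > miss_cap
  fail_het <- (ca$het < ca$hom_ref & ca$het < ca$hom_alt) |
    (co$het < co$hom_ref & co$het < co$hom_alt)

  reason <- rep(NA_character_, ncol(genotypes))
  reason[fail_het] <- "het_lt_homs"
  reason[fail_miss] <- "missingness"
  reason[fail_maf] <- "maf_gt_threshold"

  ids <- colnames(genotypes)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(genotypes)))
  data.frame(id = ids,
             miss_case = ca$miss, miss_control = co$miss,
             het_case = ca$het, hom_ref_case = ca$hom_ref,
             hom_alt_case = ca$hom_alt,
             het_control = co$het, hom_ref_control = co$hom_ref,
             hom_alt_control = co$hom_alt,
             maf_case = ca$maf, maf_control = co$maf,
             pass = is.na(reason), reason = reason,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Impute missing allele counts to the genotyped mean
#'
#' Replaces each missing call by the mean allele count among genotyped
#' subjects for that variant, so an ungenotyped subject contributes
#' `weight * mean allele count` to the burden score. Applied after QC, so
#' every variant has called genotypes.
#'
#' @inheritParams allele_counts
#' @return Numeric matrix of allele counts with no `NA` (hemizygote
#'   doubling already applied).
#' @export
imputed_allele_counts <- function(genotypes, is_x = NULL, is_male = NULL) {
  counts <- allele_counts(genotypes, is_x, is_male)
  mu <- colMeans(counts, na.rm = TRUE)
  if (any(is.nan(mu))) {
    stop("variant(s) with no called genotypes; run QC first")
  }
  nas <- which(is.na(counts), arr.ind = TRUE)
  if (nrow(nas) > 0) counts[nas] <- mu[nas[, 2]]
  counts
}

#' Gene-wise weighted burden scores
#'
#' For each gene, each subject's score is the sum over qualifying variants
#' of the variant weight times the subject's allele count, with missing
#' calls imputed to the variant's mean allele count and male X hemizygotes
#' counted as homozygotes.
#'
#' @inheritParams allele_counts
#' @param variants Data.frame of qualifying variants with columns `id`
#'   (matching `colnames(genotypes)`), `gene` and `weight`; an `is_x`
#'   logical column or a `chrom` column (X coded `"X"`) marks X-chromosome
#'   variants.
#' @return List of class `wb_scores`: `scores` (numeric matrix subjects x
#'   genes), `n_variants` (named integer, qualifying variants per gene) and
#'   `variant_ids` (list of the ids entering each gene).
#' @export
gene_burden_scores <- function(genotypes, variants, is_male = NULL) {
  stopifnot(is.data.frame(variants),
            all(c("id", "gene", "weight") %in% names(variants)))
  if (any(variants$weight < 0)) stop("variant weights must be non-negative")
  if ("is_x" %in% names(variants)) {
    vx <- as.logical(variants$is_x)
  } else if ("chrom" %in% names(variants)) {
    vx <- variants$chrom %in% c("X", "chrX", "23")
  } else {
    vx <- rep(FALSE, nrow(variants))
  }
  col <- match(variants$id, colnames(genotypes))
  if (any(is.na(col))) {
    stop("variant id(s) absent from genotype matrix: ",
         paste(utils::head(variants$id[is.na(col)]), collapse = ", "))
  }
  genes <- unique(variants$gene)
  n <- nrow(genotypes)
  scores <- matrix(0, n, length(genes),
                   dimnames = list(rownames(genotypes), genes))
  n_variants <- integer(length(genes))
  names(n_variants) <- genes
  ids <- vector("list", length(genes))
  names(ids) <- genes
  for (g in seq_along(genes)) {
    sel <- which(variants$gene == genes[g])
    sub <- genotypes[, col[sel], drop = FALSE]
    counts <- imputed_allele_counts(sub, is_x = vx[sel], is_male = is_male)
    scores[, g] <- as.vector(counts %*% variants$weight[sel])
    n_variants[g] <- length(sel)
    ids[[g]] <- variants$id[sel]
  }
  structure(list(scores = scores, n_variants = n_variants,
                 variant_ids = ids),
            class = "wb_scores")
}

#' @export
print.wb_scores <- function(x, ...) {
  cat("Gene-wise weighted burden scores:", nrow(x$scores), "subjects x",
      ncol(x$scores), "genes\n")
  cat("Qualifying variants per gene: median",
      stats::median(x$n_variants), "\n")
  invisible(x)
}
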