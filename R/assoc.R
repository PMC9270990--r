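# Gene-wise likelihood-ratio burden tests, single-variant and joint models,
# and variant-category effect decomposition.

.as_cov_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(numeric(0), n, 0))
  x <- as.matrix(covariates)
  storage.mode(x) <- "double"
  if (nrow(x) != n) stop("covariates must have one row per subject")
  if (any(is.na(x))) stop("covariates must be complete for analysed subjects")
  x
}

.fit_logit <- function(x, y, start = NULL) {
  fit <- suppressWarnings(
    stats::glm.fit(x, y, family = stats::binomial(), start = start,
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  se <- rep(NA_real_, ncol(x))
  ok <- !is.na(fit$coefficients)
  if (fit$rank > 0) {
    r <- fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE]
    r[lower.tri(r)] <- 0
    cov <- chol2inv(r)
    se[ok][seq_len(fit$rank)] <- sqrt(diag(cov))
    # glm.fit pivots: map back to original column order
    piv <- fit$qr$pivot[seq_len(fit$rank)]
    se_full <- rep(NA_real_, ncol(x))
    se_full[piv] <- sqrt(diag(cov))
    se <- se_full
  }
  list(deviance = fit$deviance, coef = fit$coefficients, se = se,
       converged = fit$converged, rank = fit$rank)
}

.slp_from <- function(p, beta) {
  if (is.na(p) || is.na(beta)) return(0)
  sign(beta) * (-log10(max(p, .Machine$double.xmin)))
}

#' Likelihood-ratio burden test for one gene
#'
#' Fits logistic regressions of case status on the covariates with and
#' without the gene-wise burden score and compares them by a
#' likelihood-ratio test on 1 degree of freedom. The result is summarized
#' as a signed log10 P value (SLP): positive when the fitted score
#' coefficient is positive (score higher in cases), negative otherwise. A
#' constant score, a collinear score or a non-converged fit yields a
#' flagged result with SLP 0.
#'
#' @param score Numeric burden score per subject.
#' @param status Case indicator (logical or 0/1).
#' @param covariates Numeric matrix or data.frame of covariates (e.g. sex
#'   and ancestry principal components); complete for analysed subjects.
#' @return One-row data.frame: `beta`, `se`, `chisq`, `p`, `slp`,
#'   `converged`, `note`.
#' @export
gene_lrt <- function(score, status, covariates = NULL) {
  status <- as.numeric(as.logical(status))
  n <- length(status)
  stopifnot(length(score) == n)
  if (!any(status == 1) || !any(status == 0)) {
    stop("both cases and controls must be present")
  }
  x0 <- cbind(`(Intercept)` = 1, .as_cov_matrix(covariates, n))
  null <- .fit_logit(x0, status)
  res <- .gene_lrt_one(score, status, x0, null)
  as.data.frame(res, stringsAsFactors = FALSE)
}

.gene_lrt_one <- function(score, status, x0, null) {
  if (stats::var(score) == 0) {
    return(list(beta = NA_real_, se = NA_real_, chisq = 0, p = 1, slp = 0,
                converged = TRUE, note = "constant_score"))
  }
  # cold start: glm.fit has no step-halving and can run away from a
  # supplied start even when the cold-started IRLS converges
  full <- .fit_logit(cbind(x0, score = score), status)
  k <- ncol(x0) + 1L
  beta <- full$coef[k]
  if (is.na(beta)) {
    return(list(beta = NA_real_, se = NA_real_, chisq = 0, p = 1, slp = 0,
                converged = full$converged, note = "collinear"))
  }
  chisq <- max(0, null$deviance - full$deviance)
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  if (!full$converged || !null$converged) {
    return(list(beta = beta, se = full$se[k], chisq = chisq, p = p, slp = 0,
                converged = FALSE, note = "non_convergence"))
  }
  list(beta = unname(beta), se = unname(full$se[k]), chisq = chisq, p = p,
       slp = .slp_from(p, beta), converged = TRUE, note = NA_character_)
}

#' Burden tests across all genes
#'
#' Runs [gene_lrt()] for every column of a score matrix, fitting the
#' covariate-only null model once.
#'
#' @param scores Numeric matrix (subjects x genes) or a `wb_scores` object
#'   from [gene_burden_scores()].
#' @inheritParams gene_lrt
#' @param n_variants Optional named integer of qualifying-variant counts
#'   (taken from the `wb_scores` object when given).
#' @return Data.frame, one row per gene, in input order: `gene`,
#'   `n_variants`, `beta`, `se`, `chisq`, `p`, `slp`, `converged`, `note`.
#' @export
burden_scan <- function(scores, status, covariates = NULL,
                        n_variants = NULL) {
  if (inherits(scores, "wb_scores")) {
    n_variants <- scores$n_variants
    scores <- scores$scores
  }
  scores <- as.matrix(scores)
  status <- as.numeric(as.logical(status))
  stopifnot(nrow(scores) == length(status))
  if (!any(status == 1) || !any(status == 0)) {
    stop("both cases and controls must be present")
  }
  x0 <- cbind(`(Intercept)` = 1, .as_cov_matrix(covariates, length(status)))
  null <- .fit_logit(x0, status)
  genes <- colnames(scores)
  if (is.null(genes)) genes <- as.character(seq_len(ncol(scores)))
  rows <- vector("list", ncol(scores))
  for (g in seq_len(ncol(scores))) {
    rows[[g]] <- .gene_lrt_one(scores[, g], status, x0, null)
  }
  out <- do.call(rbind, lapply(rows, as.data.frame,
                               stringsAsFactors = FALSE))
  out <- cbind(data.frame(gene = genes, stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  if (!is.null(n_variants)) {
    out$n_variants <- as.integer(n_variants[match(out$gene,
                                                  names(n_variants))])
    out <- out[c("gene", "n_variants", "beta", "se", "chisq", "p", "slp",
                 "converged", "note")]
  }
  attr(out, "null_deviance") <- null$deviance
  out
}

#' Covariate-adjusted tests of individual variants
#'
#' Enters the allele counts of one or more variants into a single logistic
#' regression of case status, together with the covariates. When several
#' variants are supplied they are fitted jointly, so each effect is
#' conditional on the others — the treatment used for variants in strong
#' linkage disequilibrium such as the ADH cluster. Subjects missing any
#' tested genotype are dropped. Monomorphic variants are flagged without an
#' estimate; coefficients dropped for collinearity are flagged.
#'
#' @param counts Numeric vector or subjects x variants matrix of allele
#'   counts (`NA` = missing; X-hemizygote doubling already applied, see
#'   [allele_counts()]).
#' @inheritParams gene_lrt
#' @return Data.frame per variant: `id`, `n_used`, `freq_control`,
#'   `freq_case`, `beta`, `se`, `or`, `p` (Wald), `slp`, `note`.
#' @export
variant_test <- function(counts, status, covariates = NULL) {
  counts <- as.matrix(counts)
  status <- as.numeric(as.logical(status))
  stopifnot(nrow(counts) == length(status))
  ids <- colnames(counts)
  if (is.null(ids)) ids <- paste0("v", seq_len(ncol(counts)))

  keep <- stats::complete.cases(counts)
  cnt <- counts[keep, , drop = FALSE]
  st <- status[keep]
  if (!any(st == 1) || !any(st == 0)) {
    stop("both cases and controls must be present among genotyped subjects")
  }
  freq <- function(rows) colSums(cnt[rows, , drop = FALSE]) / (2 * sum(rows))
  out <- data.frame(id = ids, n_used = sum(keep),
                    freq_control = freq(st == 0), freq_case = freq(st == 1),
                    beta = NA_real_, se = NA_real_, or = NA_real_,
                    p = NA_real_, slp = NA_real_, note = NA_character_,
                    stringsAsFactors = FALSE, row.names = NULL)
  mono <- apply(cnt, 2, stats::var) == 0
  out$note[mono] <- "monomorphic"
  if (all(mono)) return(out)

  x <- cbind(`(Intercept)` = 1, .as_cov_matrix(covariates[keep, , drop = FALSE],
                                               sum(keep)),
             cnt[, !mono, drop = FALSE])
  fit <- .fit_logit(x, st)
  k0 <- ncol(x) - sum(!mono)
  idx <- which(!mono)
  for (j in seq_along(idx)) {
    b <- fit$coef[k0 + j]
    if (is.na(b)) {
      out$note[idx[j]] <- "collinear"
      next
    }
    se <- fit$se[k0 + j]
    p <- 2 * stats::pnorm(abs(b / se), lower.tail = FALSE)
    out$beta[idx[j]] <- b
    out$se[idx[j]] <- se
    out$or[idx[j]] <- exp(b)
    out$p[idx[j]] <- p
    out$slp[idx[j]] <- .slp_from(p, b)
    if (!fit$converged) out$note[idx[j]] <- "non_convergence"
  }
  out
}

#' Variant-category effect decomposition for a gene
#'
#' Builds, for each broad annotation category present among a gene's
#' qualifying variants (categories marked "Unused" are excluded), a
#' per-subject covariate counting the unweighted alleles of that category,
#' and fits all category counts jointly in one covariate-adjusted logistic
#' regression (optionally with extra individual-variant covariates, as for
#' conditioning on known ADH-cluster variants). Each category's odds ratio
#' and standard error come from this model; its P value is the Wald test,
#' except that categories whose alleles occur fewer than `fisher_threshold`
#' times (default 50) use Fisher's exact test on the 2x2 table of category
#' alleles versus remaining chromosomes in cases and controls.
#'
#' @param genotypes Subjects x variants genotype matrix (qualifying
#'   variants of the gene).
#' @param variants Data.frame with columns `id`, `category` and optionally
#'   `is_x`/`chrom` for the gene's qualifying variants.
#' @inheritParams gene_lrt
#' @param is_male Logical per subject for X-hemizygote handling.
#' @param extra_counts Optional numeric matrix of additional allele-count
#'   covariates entered alongside the categories.
#' @param fisher_threshold Minimum category allele count for the Wald test.
#' @return Data.frame per category: `category`, `n_variants`,
#'   `occurrences`, `beta`, `se`, `or`, `p`, `test` (`"wald"` or
#'   `"fisher_exact"`).
#' @export
category_decomposition <- function(genotypes, variants, status,
                                   covariates = NULL, is_male = NULL,
                                   extra_counts = NULL,
                                   fisher_threshold = 50) {
  stopifnot(all(c("id", "category") %in% names(variants)))
  status <- as.numeric(as.logical(status))
  if ("is_x" %in% names(variants)) {
    vx <- as.logical(variants$is_x)
  } else if ("chrom" %in% names(variants)) {
    vx <- variants$chrom %in% c("X", "chrX", "23")
  } else {
    vx <- rep(FALSE, nrow(variants))
  }
  use <- variants$category != "Unused"
  variants <- variants[use, , drop = FALSE]
  vx <- vx[use]
  col <- match(variants$id, colnames(genotypes))
  if (any(is.na(col))) stop("variant id(s) absent from genotype matrix")
  counts <- allele_counts(genotypes[, col, drop = FALSE], vx, is_male)
  counts[is.na(counts)] <- 0  # missing treated as non-carrier for counts

  cats <- unique(variants$category)
  cat_counts <- sapply(cats, function(cc) {
    rowSums(counts[, variants$category == cc, drop = FALSE])
  })
  cat_counts <- matrix(cat_counts, nrow = nrow(genotypes),
                       dimnames = list(NULL, cats))
  occ <- colSums(cat_counts)
  present <- occ > 0
  out <- data.frame(category = cats,
                    n_variants = as.integer(table(variants$category)[cats]),
                    occurrences = occ,
                    beta = NA_real_, se = NA_real_, or = NA_real_,
                    p = NA_real_, test = NA_character_,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!any(present)) return(out[present, , drop = FALSE])
  out <- out[present, , drop = FALSE]
  cat_counts <- cat_counts[, present, drop = FALSE]

  x <- cbind(`(Intercept)` = 1,
             .as_cov_matrix(covariates, length(status)))
  if (!is.null(extra_counts)) {
    x <- cbind(x, as.matrix(extra_counts))
  }
  k0 <- ncol(x)
  fit <- .fit_logit(cbind(x, cat_counts), status)
  n_case <- sum(status == 1)
  n_control <- sum(status == 0)
  for (j in seq_len(ncol(cat_counts))) {
    b <- fit$coef[k0 + j]
    if (!is.na(b)) {
      out$beta[j] <- b
      out$se[j] <- fit$se[k0 + j]
      out$or[j] <- exp(b)
    }
    if (out$occurrences[j] < fisher_threshold) {
      a_case <- sum(cat_counts[status == 1, j])
      a_control <- sum(cat_counts[status == 0, j])
      tab <- matrix(c(a_case, 2 * n_case - a_case,
                      a_control, 2 * n_control - a_control),
                    nrow = 2, byrow = TRUE)
      out$p[j] <- stats::fisher.test(round(tab))$p.value
      out$test[j] <- "fisher_exact"
    } else if (!is.na(b)) {
      out$p[j] <- 2 * stats::pnorm(abs(b / out$se[j]), lower.tail = FALSE)
      out$test[j] <- "wald"
    }
  }
  out
}

#' Exome-wide Bonferroni threshold on the SLP scale
#'
#' The absolute SLP above which a gene-wise result remains significant
#' after correcting for the number of genes tested times the number of
#' phenotypes: `-log10(alpha / (n_genes * n_phenotypes))`.
#'
#' @param n_genes Number of genes with qualifying variants.
#' @param n_phenotypes Number of phenotypes analysed.
#' @param alpha Family-wise error rate.
#' @return The critical |SLP|.
#' @examples
#' bonferroni_slp_threshold(20384, 2)  # 5.91
#' @export
bonferroni_slp_threshold <- function(n_genes, n_phenotypes = 1,
                                     alpha = 0.05) {
  stopifnot(n_genes > 0, n_phenotypes > 0, alpha > 0, alpha <= 1)
  -log10(alpha / (n_genes * n_phenotypes))
}
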