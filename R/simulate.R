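# Synthetic stratified-cohort generator: rare variants with realistic
# annotation mixtures, subpopulation allele-frequency divergence, PC-like
# ancestry covariates, sex, missing genotypes, and case status drawn from a
# logistic model with configurable per-gene burden effects.

#' Configuration for a synthetic cohort
#'
#' Defaults describe a modest stratified exome cohort: two subpopulations
#' with Balding-Nichols allele-frequency divergence, rare variants with MAF
#' drawn from a truncated exponential on (0, 0.01], an exome-like mixture
#' of consequence terms, 20 PC-like ancestry covariates, genotypes missing
#' completely at random at 0.5%, and a baseline case prevalence of 0.09
#' (roughly the heavy-drinking case fraction in a large biobank cohort).
#'
#' @param n_subjects,n_genes Positive counts.
#' @param variants_per_gene Variants simulated per gene.
#' @param maf_distribution Either `list(rate =, max =)` for a truncated
#'   exponential on (0, max] (default rate 500, max 0.01 — mean MAF about
#'   0.002) or `list(fixed =)` for a single shared MAF.
#' @param category_mixture Named probabilities over consequence terms
#'   (must sum to 1; all terms must appear in [annotation_weights()]).
#' @param polyphen_probs,sift_probs Named probabilities for the PolyPhen
#'   (`none`/`possibly`/`probably`) and SIFT (`none`/`deleterious`)
#'   predictions attached to protein-altering variants.
#' @param n_subpopulations Number of discrete ancestry strata (>= 1).
#' @param subpop_frequency_divergence Balding-Nichols F (Fst-like) scalar
#'   controlling between-population MAF differences; 0 disables divergence.
#' @param missing_rate Completely-at-random genotype missingness in
#'   \[0, 1).
#' @param x_gene_fraction Probability that a gene lies on the X chromosome
#'   (males are then simulated hemizygous).
#' @param causal_genes Named numeric: log-odds effect per gene, applied to
#'   that gene's true weighted burden score (names must match simulated
#'   gene symbols, `GENE0001`...). Empty for a null cohort.
#' @param effect_scale `"per_sd"` (default; the causal effect multiplies
#'   the score standardized to unit SD, keeping odds ratios in a realistic
#'   range) or `"per_unit"` (raw weighted score).
#' @param baseline_prevalence Case probability at covariate value zero.
#' @param covariate_effects List with `sex` (log-odds for male sex) and
#'   `pc` (numeric, recycled/truncated to `n_pcs`, log-odds per PC unit).
#' @param n_pcs Number of PC covariates generated.
#' @param pc_signal Separation of subpopulation means on the informative
#'   PCs, in units of the within-population (unit) noise SD.
#' @param seed Integer RNG seed; identical config + seed reproduces the
#'   cohort exactly.
#' @return Validated list of class `wb_sim_config`.
#' @export
sim_config <- function(n_subjects = 5000,
                       n_genes = 100,
                       variants_per_gene = 6,
                       maf_distribution = list(rate = 500, max = 0.01),
                       category_mixture = c(
                         synonymous_variant = 0.30,
                         missense_variant = 0.40,
                         intron_variant = 0.05,
                         splice_region_variant = 0.06,
                         "5_prime_UTR_variant" = 0.03,
                         "3_prime_UTR_variant" = 0.03,
                         inframe_deletion = 0.02,
                         inframe_insertion = 0.01,
                         frameshift_variant = 0.04,
                         stop_gained = 0.03,
                         splice_donor_variant = 0.015,
                         splice_acceptor_variant = 0.015),
                       polyphen_probs = c(none = 0.45, possibly = 0.30,
                                          probably = 0.25),
                       sift_probs = c(none = 0.55, deleterious = 0.45),
                       n_subpopulations = 2,
                       subpop_frequency_divergence = 0.02,
                       missing_rate = 0.005,
                       x_gene_fraction = 0.04,
                       causal_genes = numeric(0),
                       effect_scale = c("per_sd", "per_unit"),
                       baseline_prevalence = 0.09,
                       covariate_effects = list(sex = 0.2,
                                                pc = c(0.5, rep(0, 19))),
                       n_pcs = 20,
                       pc_signal = 3,
                       seed = 1) {
  effect_scale <- match.arg(effect_scale)
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_genes = as.integer(n_genes),
              variants_per_gene = as.integer(variants_per_gene),
              maf_distribution = maf_distribution,
              category_mixture = category_mixture,
              polyphen_probs = polyphen_probs,
              sift_probs = sift_probs,
              n_subpopulations = as.integer(n_subpopulations),
              subpop_frequency_divergence = subpop_frequency_divergence,
              missing_rate = missing_rate,
              x_gene_fraction = x_gene_fraction,
              causal_genes = causal_genes,
              effect_scale = effect_scale,
              baseline_prevalence = baseline_prevalence,
              covariate_effects = covariate_effects,
              n_pcs = as.integer(n_pcs),
              pc_signal = pc_signal,
              seed = as.integer(seed))
  class(cfg) <- "wb_sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param config A `wb_sim_config` list to validate.
#' @export
validate_sim_config <- function(config) {
  with(config, {
    if (n_subjects < 1) stop("n_subjects must be positive")
    if (n_genes < 1) stop("n_genes must be positive")
    if (variants_per_gene < 1) stop("variants_per_gene must be positive")
    if (!is.null(maf_distribution$fixed)) {
      if (maf_distribution$fixed <= 0 || maf_distribution$fixed > 0.01) {
        stop("fixed MAF must lie in (0, 0.01]")
      }
    } else {
      if (is.null(maf_distribution$rate) || maf_distribution$rate <= 0) {
        stop("maf_distribution needs a positive rate (or a fixed value)")
      }
      if (is.null(maf_distribution$max) || maf_distribution$max <= 0 ||
          maf_distribution$max > 0.01) {
        stop("maf_distribution max must lie in (0, 0.01]")
      }
    }
    for (pv in list(category_mixture, polyphen_probs, sift_probs)) {
      if (any(pv < 0) || abs(sum(pv) - 1) > 1e-8) {
        stop("probability vectors must be non-negative and sum to 1")
      }
    }
    tab <- annotation_weights()
    .match_consequence(names(category_mixture), tab)
    if (n_subpopulations < 1) stop("n_subpopulations must be >= 1")
    if (subpop_frequency_divergence < 0) {
      stop("subpop_frequency_divergence must be non-negative")
    }
    if (missing_rate < 0 || missing_rate >= 1) {
      stop("missing_rate must lie in [0, 1)")
    }
    if (baseline_prevalence <= 0 || baseline_prevalence >= 1) {
      stop("baseline_prevalence must lie in (0, 1)")
    }
    if (length(causal_genes) > 0 &&
        (is.null(names(causal_genes)) || any(!nzchar(names(causal_genes))))) {
      stop("causal_genes must be a named numeric vector")
    }
    if (n_pcs < 0) stop("n_pcs must be non-negative")
  })
  invisible(config)
}

.sim_gene_names <- function(n_genes) {
  sprintf("GENE%0*d", max(4L, nchar(n_genes)), seq_len(n_genes))
}

#' Simulate a stratified rare-variant cohort
#'
#' Draws, under the given configuration: gene/variant definitions with
#' annotation triples; per-subpopulation allele frequencies from a
#' Balding-Nichols model capped at the rare-variant MAF limit; genotypes as
#' binomial(2, subpopulation MAF) on autosomes and binomial(1, MAF) for
#' males on the X chromosome; PC covariates as noisy linear encodings of
#' subpopulation membership; sex as Bernoulli(0.5) independent of
#' ancestry; case status from a logistic model combining the baseline
#' prevalence, sex and PC effects and the configured causal-gene effects
#' applied to true weighted burden scores; and finally
#' completely-at-random genotype missingness. Identical config and seed
#' give bit-identical output.
#'
#' @param config A [sim_config()] object.
#' @return List of class `wb_cohort`: `genotypes` (subjects x variants
#'   integer matrix with `NA` for missing), `variants` (id, gene, chrom,
#'   pos, ref, alt, consequence, polyphen, sift, `maf_true` pooled
#'   generative MAF; per-subpopulation frequencies in `attr(, "pop_maf")`),
#'   `cohort` (subject, sex with male = 1, subpop, PC columns, `case`),
#'   `true_scores` (matrix of the causal genes' generative burden
#'   covariates, on the scale the effect was applied; `NULL` for null
#'   cohorts) and the `config`.
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_subjects
  n_genes <- config$n_genes
  vpg <- config$variants_per_gene
  nv <- n_genes * vpg

  genes <- .sim_gene_names(n_genes)
  if (length(config$causal_genes) > 0 &&
      !all(names(config$causal_genes) %in% genes)) {
    stop("causal gene(s) not among simulated genes: ",
         paste(setdiff(names(config$causal_genes), genes), collapse = ", "))
  }
  gene_chrom <- ifelse(stats::runif(n_genes) < config$x_gene_fraction, "X",
                       as.character(sample(1:22, n_genes, replace = TRUE)))

  variants <- data.frame(
    id = sprintf("var%0*d", max(6L, nchar(nv)), seq_len(nv)),
    gene = rep(genes, each = vpg),
    chrom = rep(gene_chrom, each = vpg),
    pos = rep((seq_len(n_genes) - 1) * 100000L, each = vpg) +
      as.integer(sequence(rep(vpg, n_genes)) * 150L) +
      sample(1:100, nv, replace = TRUE),
    ref = sample(c("A", "C", "G", "T"), nv, replace = TRUE),
    stringsAsFactors = FALSE)
  variants$alt <- vapply(variants$ref, function(r) {
    sample(setdiff(c("A", "C", "G", "T"), r), 1)
  }, character(1))
  variants$consequence <- sample(names(config$category_mixture), nv,
                                 replace = TRUE,
                                 prob = config$category_mixture)
  tab <- annotation_weights()
  protein <- variant_category(variants$consequence, tab) == "Protein altering"
  variants$polyphen <- "none"
  variants$sift <- "none"
  if (any(protein)) {
    variants$polyphen[protein] <- sample(names(config$polyphen_probs),
                                         sum(protein), replace = TRUE,
                                         prob = config$polyphen_probs)
    variants$sift[protein] <- sample(names(config$sift_probs),
                                     sum(protein), replace = TRUE,
                                     prob = config$sift_probs)
  }

  md <- config$maf_distribution
  if (!is.null(md$fixed)) {
    base_maf <- rep(md$fixed, nv)
  } else {
    u <- stats::runif(nv, 0, stats::pexp(md$max, md$rate))
    base_maf <- pmin(stats::qexp(u, md$rate), md$max)
  }

  K <- config$n_subpopulations
  fst <- config$subpop_frequency_divergence
  if (K > 1 && fst > 0) {
    pop_maf <- matrix(stats::rbeta(nv * K,
                                   rep(base_maf, K) * (1 - fst) / fst,
                                   rep(1 - base_maf, K) * (1 - fst) / fst),
                      nrow = nv, ncol = K)
    cap <- if (!is.null(md$fixed)) 0.01 else md$max
    pop_maf <- pmin(pop_maf, cap)
  } else {
    pop_maf <- matrix(base_maf, nrow = nv, ncol = K)
  }

  subpop <- sample.int(K, n, replace = TRUE)
  male <- stats::rbinom(n, 1, 0.5)
  is_x <- variants$chrom == "X"

  geno <- matrix(0L, n, nv,
                 dimnames = list(sprintf("S%0*d", max(5L, nchar(n)),
                                         seq_len(n)),
                                 variants$id))
  for (k in seq_len(K)) {
    rows <- which(subpop == k)
    if (length(rows) == 0) next
    geno[rows, ] <- matrix(
      stats::rbinom(length(rows) * nv, 2L,
                    rep(pop_maf[, k], each = length(rows))),
      nrow = length(rows))
    if (any(is_x)) {
      mrows <- rows[male[rows] == 1]
      if (length(mrows) > 0) {
        geno[mrows, is_x] <- matrix(
          stats::rbinom(length(mrows) * sum(is_x), 1L,
                        rep(pop_maf[is_x, k], each = length(mrows))),
          nrow = length(mrows))
      }
    }
  }

  pcs <- matrix(stats::rnorm(n * config$n_pcs), n, config$n_pcs)
  if (config$n_pcs > 0) {
    for (j in seq_len(min(K - 1, config$n_pcs))) {
      ind <- as.numeric(subpop == j + 1)
      pcs[, j] <- config$pc_signal * (ind - mean(ind)) + stats::rnorm(n)
    }
    colnames(pcs) <- paste0("PC", seq_len(config$n_pcs))
  }

  # pooled generative MAF and true weights (used for causal effects)
  props <- tabulate(subpop, K) / n
  maf_pool <- as.vector(pop_maf %*% props)
  w_true <- functional_weight(variants$consequence, variants$polyphen,
                              variants$sift, tab) *
    maf_weight(pmin(maf_pool, 0.01))

  eta <- rep(stats::qlogis(config$baseline_prevalence), n) +
    config$covariate_effects$sex * male
  if (config$n_pcs > 0) {
    pc_eff <- rep_len(config$covariate_effects$pc, config$n_pcs)
    eta <- eta + as.vector(pcs %*% pc_eff)
  }
  true_scores <- NULL
  if (length(config$causal_genes) > 0) {
    counts <- NULL
    true_scores <- matrix(0, n, length(config$causal_genes),
                          dimnames = list(NULL,
                                          names(config$causal_genes)))
    for (g in names(config$causal_genes)) {
      sel <- which(variants$gene == g)
      cnt <- allele_counts(geno[, sel, drop = FALSE], is_x[sel],
                           male == 1)
      s <- as.vector(cnt %*% w_true[sel])
      if (config$effect_scale == "per_sd") {
        sdev <- stats::sd(s)
        if (sdev > 0) s <- s / sdev else
          warning("causal gene ", g, " has constant burden score")
      }
      true_scores[, g] <- s
      eta <- eta + config$causal_genes[[g]] * s
    }
  }
  case <- stats::rbinom(n, 1, stats::plogis(eta))

  if (config$missing_rate > 0) {
    n_miss <- stats::rbinom(1, n * nv, config$missing_rate)
    if (n_miss > 0) {
      geno[sample.int(n * nv, n_miss)] <- NA_integer_
    }
  }

  variants$maf_true <- maf_pool
  attr(variants, "pop_maf") <- pop_maf
  cohort <- data.frame(subject = rownames(geno), sex = male,
                       subpop = subpop, stringsAsFactors = FALSE)
  if (config$n_pcs > 0) cohort <- cbind(cohort, as.data.frame(pcs))
  cohort$case <- case

  structure(list(genotypes = geno, variants = variants, cohort = cohort,
                 true_scores = true_scores, config = config),
            class = "wb_cohort")
}

#' @export
print.wb_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$genotypes), "subjects,",
      ncol(x$genotypes), "variants in", x$config$n_genes, "genes\n")
  cat("  cases:", sum(x$cohort$case), " controls:",
      sum(1 - x$cohort$case), "\n")
  cat("  subpopulations:", x$config$n_subpopulations,
      " causal genes:", length(x$config$causal_genes),
      " seed:", x$config$seed, "\n")
  invisible(x)
}
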