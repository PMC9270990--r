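# Fisher's-method gene-set analysis over gene-wise burden-test P values.

#' Combine P values by Fisher's method
#'
#' For k independent P values, `-2 * sum(ln p)` follows a chi-squared
#' distribution with `2k` degrees of freedom under the joint null.
#'
#' @param p Numeric vector of P values, each in (0, 1]. A zero is an error:
#'   callers must floor vanishingly small P values first (see
#'   [set_scan()]).
#' @return List: `chisq`, `df`, `p`.
#' @examples
#' fisher_method(c(0.05, 0.2))
#' @export
fisher_method <- function(p) {
  if (length(p) == 0) stop("need at least one P value")
  if (any(is.na(p)) || any(p > 1)) stop("P values must lie in (0, 1]")
  if (any(p <= 0)) {
    stop("P value of 0 (or negative); floor tiny P values upstream")
  }
  chisq <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(chisq = chisq, df = df,
       p = stats::pchisq(chisq, df = df, lower.tail = FALSE))
}

#' Read gene sets from a GMT file
#'
#' Parses the tab-separated GMT format (set name, description, member gene
#' symbols) used by MSigDB collections such as the GO gene-set file.
#' Members are deduplicated; sets with no members are dropped.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of member gene symbols.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1)) < 3
  if (any(short)) {
    stop("malformed GMT line(s) (need name, description, >=1 member): ",
         paste(utils::head(which(short)), collapse = ", "))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, character(1), 1)
  if (anyDuplicated(names(sets)) > 0) {
    stop("duplicated set names in GMT file")
  }
  sets
}

#' Gene-set scan by Fisher's method
#'
#' For each gene set, combines the gene-wise P values of its scored members
#' with [fisher_method()], giving a chi-squared statistic on twice the
#' number of scored genes degrees of freedom. Set members without a
#' gene-wise result are dropped from that set (and counted); sets with no
#' scored member are skipped with a warning. Gene P values are floored at
#' `p_floor` before taking logs.
#'
#' @param gene_results Data.frame with columns `gene` and `p` (two-sided
#'   gene-wise P values, e.g. from [burden_scan()]).
#' @param sets Named list of member-gene character vectors (see
#'   [read_gmt()]) .
#' @param n_phenotypes Number of phenotypes analysed, entering the
#'   Bonferroni threshold `alpha / (n_sets * n_phenotypes)`.
#' @param alpha Family-wise error rate for the threshold.
#' @param p_floor Smallest admissible gene-wise P value.
#' @return Data.frame per set: `set`, `n_scored`, `n_unscored`, `chisq`,
#'   `df`, `p`; the Bonferroni threshold is in `attr(, "threshold")`.
#' @export
set_scan <- function(gene_results, sets, n_phenotypes = 1, alpha = 0.05,
                     p_floor = 1e-300) {
  stopifnot(all(c("gene", "p") %in% names(gene_results)),
            length(sets) > 0, !is.null(names(sets)))
  pvals <- pmax(gene_results$p, p_floor)
  names(pvals) <- gene_results$gene
  rows <- lapply(names(sets), function(nm) {
    members <- unique(sets[[nm]])
    scored <- members[members %in% names(pvals)]
    if (length(scored) == 0) {
      warning("set '", nm, "' has no scored member genes; skipped")
      return(data.frame(set = nm, n_scored = 0L,
                        n_unscored = length(members),
                        chisq = NA_real_, df = NA_integer_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    fm <- fisher_method(pvals[scored])
    data.frame(set = nm, n_scored = length(scored),
               n_unscored = length(members) - length(scored),
               chisq = fm$chisq, df = fm$df, p = fm$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- alpha / (length(sets) * n_phenotypes)
  out
}
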