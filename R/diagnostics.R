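# Calibration diagnostics for the SLP distribution and chi-squared-based
# sample-size extrapolation.

#' Null quantiles of the signed log10 P statistic
#'
#' Under the null the SLP is symmetric around zero with tail law
#' `P(SLP >= x) = P(SLP <= -x) = 0.5 * 10^-x` for `x >= 0` (a uniform P
#' value carrying a random sign). This returns the `n` null quantiles at
#' plotting positions `(i - 0.5) / n`.
#'
#' @param n Number of quantiles.
#' @return Numeric vector of expected SLPs, increasing.
#' @export
expected_slp_quantiles <- function(n) {
  stopifnot(n >= 1)
  p <- (seq_len(n) - 0.5) / n
  ifelse(p < 0.5, log10(2 * p), -log10(2 * (1 - p)))
}

#' QQ summary of observed versus expected SLPs
#'
#' Pairs the sorted observed SLPs with the null quantiles of
#' [expected_slp_quantiles()], drops the `n_exclude` highest and
#' `n_exclude` lowest observed SLPs at each end (which may carry real
#' signal), and fits separate ordinary least-squares lines through the
#' negative-expected and positive-expected branches. A well-calibrated
#' null gives gradient 1 and intercept 0 on both branches.
#'
#' @param slp Numeric vector of gene-wise SLPs.
#' @param n_exclude Number of extreme genes to drop at each end (by rank of
#'   observed SLP).
#' @return Object of class `wb_qq`: `branches` (data.frame with `branch`,
#'   `gradient`, `intercept`, `n_used`) and `points` (per-gene `expected`,
#'   `observed`, `branch`, `excluded`).
#' @export
qq_summary <- function(slp, n_exclude = 100) {
  slp <- as.numeric(slp)
  if (any(is.na(slp))) stop("slp must not contain NA")
  n <- length(slp)
  if (n < 2 * n_exclude + 2) {
    stop("need at least 2 * n_exclude + 2 SLPs (got ", n, ")")
  }
  obs <- sort(slp)
  exp_q <- expected_slp_quantiles(n)
  excluded <- rep(FALSE, n)
  if (n_exclude > 0) {
    excluded[seq_len(n_exclude)] <- TRUE
    excluded[seq(n - n_exclude + 1, n)] <- TRUE
  }
  branch <- ifelse(exp_q < 0, "negative", "positive")
  fit_branch <- function(b) {
    keep <- branch == b & !excluded
    if (sum(keep) < 2) {
      return(data.frame(branch = b, gradient = NA_real_,
                        intercept = NA_real_, n_used = sum(keep)))
    }
    co <- stats::coef(stats::lm(obs[keep] ~ exp_q[keep]))
    data.frame(branch = b, gradient = unname(co[2]),
               intercept = unname(co[1]), n_used = sum(keep),
               stringsAsFactors = FALSE)
  }
  structure(list(
    branches = rbind(fit_branch("negative"), fit_branch("positive")),
    points = data.frame(expected = exp_q, observed = obs, branch = branch,
                        excluded = excluded, stringsAsFactors = FALSE)),
    class = "wb_qq")
}

#' @export
print.wb_qq <- function(x, ...) {
  cat("QQ summary of SLPs (", nrow(x$points), " genes, ",
      sum(x$points$excluded), " excluded as extremes)\n", sep = "")
  for (i in seq_len(nrow(x$branches))) {
    b <- x$branches[i, ]
    cat(sprintf("  %s branch: gradient %.3f, intercept %.3f (n = %d)\n",
                b$branch, b$gradient, b$intercept, b$n_used))
  }
  invisible(x)
}

#' @export
plot.wb_qq <- function(x, ...) {
  pts <- x$points
  graphics::plot(pts$expected, pts$observed,
                 col = ifelse(pts$excluded, "grey70",
                              ifelse(pts$branch == "positive",
                                     "firebrick", "steelblue")),
                 pch = 20, xlab = "Expected SLP", ylab = "Observed SLP", ...)
  graphics::abline(0, 1, lty = 2)
  for (i in seq_len(nrow(x$branches))) {
    b <- x$branches[i, ]
    if (!is.na(b$gradient)) graphics::abline(b$intercept, b$gradient)
  }
  invisible(x)
}

#' Expected number of genes past a P-value threshold under the null
#'
#' @param n_genes Number of genes tested.
#' @param p_threshold Two-sided P-value threshold.
#' @return `n_genes * p_threshold`, e.g. about 20 genes at |SLP| > 3 among
#'   20,384 genes.
#' @export
expected_exceedance <- function(n_genes, p_threshold) {
  stopifnot(n_genes > 0, p_threshold >= 0, p_threshold <= 1)
  n_genes * p_threshold
}

#' Chi-squared statistic equivalent to an SLP
#'
#' The 1-df likelihood-ratio chi-squared whose upper-tail probability is
#' `10^-|slp|`; the inverse of the chi-squared-to-SLP-magnitude map of the
#' burden test.
#'
#' @param slp Signed log10 P value(s).
#' @return Non-negative chi-squared value(s).
#' @examples
#' slp_to_chisq(4.59)  # 17.7
#' @export
slp_to_chisq <- function(slp) {
  stopifnot(all(is.finite(slp)))
  stats::qchisq(10^(-abs(slp)), df = 1, lower.tail = FALSE)
}

#' Sample-size multiplier to reach a target SLP
#'
#' Assuming the observed 1-df chi-squared reflects a real effect, its
#' noncentrality scales linearly with sample size, so the factor by which
#' the sample must grow for the expected statistic to reach the value
#' equivalent to `target_slp` is `slp_to_chisq(target_slp) /
#' observed_chisq`.
#'
#' @param observed_chisq Observed positive 1-df chi-squared.
#' @param target_slp Target |SLP| (e.g. the exome-wide threshold).
#' @return The multiplier.
#' @examples
#' sample_multiplier(17.7, 5.91)  # 1.3
#' @export
sample_multiplier <- function(observed_chisq, target_slp) {
  stopifnot(target_slp > 0)
  if (any(observed_chisq <= 0)) {
    stop("observed chi-squared must be positive")
  }
  slp_to_chisq(target_slp) / observed_chisq
}
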