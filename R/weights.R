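# Functional-annotation and MAF-based variant weighting.

.modifier_terms <- c(sift_deleterious   = "SIFT_deleterious",
                     polyphen_possibly  = "PolyPhen_possibly_damaging",
                     polyphen_probably  = "PolyPhen_probably_damaging")

#' Functional annotation weight table
#'
#' Loads the table mapping each VEP consequence term to a functional weight
#' and to the broad category used in variant-category decompositions. The
#' packaged default assigns 100 to loss-of-function consequences
#' (frameshift, stop gained, canonical splice sites, transcript ablation),
#' 10 to in-frame indels, 5 to non-synonymous changes and 0 to synonymous or
#' intronic changes. Three modifier rows (`SIFT_deleterious`,
#' `PolyPhen_possibly_damaging`, `PolyPhen_probably_damaging`) hold the
#' weights *added* to protein-altering variants carrying those predictions;
#' they are not themselves consequence terms.
#'
#' @param file Path to an alternative tab-separated table with columns
#'   `consequence`, `weight`, `category` (same schema as the packaged
#'   default, which is used when `file` is `NULL`).
#' @return A data.frame with columns `consequence`, `weight`, `category`.
#' @examples
#' head(annotation_weights())
#' @export
annotation_weights <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "annotation_weights.tsv",
                        package = "wburden", mustWork = TRUE)
  }
  tab <- utils::read.delim(file, comment.char = "#",
                           check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("consequence", "weight", "category")
  if (!all(need %in% names(tab))) {
    stop("weight table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tab$consequence) > 0) {
    stop("duplicated consequence terms in weight table: ",
         paste(unique(tab$consequence[duplicated(tab$consequence)]),
               collapse = ", "))
  }
  if (!is.numeric(tab$weight) || any(!is.finite(tab$weight)) ||
      any(tab$weight < 0)) {
    stop("weights must be finite and non-negative")
  }
  if (!all(.modifier_terms %in% tab$consequence)) {
    stop("weight table is missing modifier rows: ",
         paste(setdiff(.modifier_terms, tab$consequence), collapse = ", "))
  }
  tab
}

.match_consequence <- function(consequence, table) {
  valid <- setdiff(table$consequence, .modifier_terms)
  idx <- match(consequence, table$consequence)
  bad <- is.na(idx) | table$consequence[idx] %in% .modifier_terms
  if (any(bad)) {
    stop("unknown consequence term(s): ",
         paste(unique(consequence[bad]), collapse = ", "),
         "\nvalid terms: ", paste(valid, collapse = ", "))
  }
  idx
}

.modifier_weight <- function(which, table) {
  table$weight[match(.modifier_terms[[which]], table$consequence)]
}

#' Functional weight of a variant
#'
#' Base weight from the consequence term, plus additive modifiers for
#' protein-altering variants: PolyPhen "possibly damaging" and "probably
#' damaging" predictions add their respective weights (mutually exclusive,
#' 5 and 10 by default) and a SIFT "deleterious" prediction adds a further
#' 20. Modifiers never apply to non-protein-altering consequences, so a
#' synonymous or intronic variant scores 0 regardless of its PolyPhen/SIFT
#' fields.
#'
#' @param consequence Character vector of VEP consequence terms.
#' @param polyphen One of `"none"`, `"possibly"`, `"probably"` per variant
#'   (`NA` treated as `"none"`).
#' @param sift One of `"none"`, `"deleterious"` per variant (`NA` treated as
#'   `"none"`).
#' @param table Weight table as returned by [annotation_weights()].
#' @return Numeric vector of non-negative functional weights.
#' @examples
#' functional_weight("frameshift_variant")                      # 100
#' functional_weight("missense_variant", "probably", "deleterious")  # 35
#' @export
functional_weight <- function(consequence, polyphen = "none", sift = "none",
                              table = annotation_weights()) {
  n <- length(consequence)
  polyphen <- rep_len(as.character(polyphen), n)
  sift <- rep_len(as.character(sift), n)
  polyphen[is.na(polyphen)] <- "none"
  sift[is.na(sift)] <- "none"
  if (!all(polyphen %in% c("none", "possibly", "probably"))) {
    stop("polyphen must be one of: none, possibly, probably")
  }
  if (!all(sift %in% c("none", "deleterious"))) {
    stop("sift must be one of: none, deleterious")
  }
  idx <- .match_consequence(consequence, table)
  w <- table$weight[idx]
  protein <- table$category[idx] == "Protein altering"
  w <- w +
    protein * (polyphen == "possibly") * .modifier_weight("polyphen_possibly", table) +
    protein * (polyphen == "probably") * .modifier_weight("polyphen_probably", table) +
    protein * (sift == "deleterious") * .modifier_weight("sift_deleterious", table)
  as.numeric(w)
}

#' Broad category of a consequence term
#'
#' Returns the category column of the weight table ("Disruptive",
#' "Protein altering", "Synonymous", ...) used to group variants in
#' category decompositions. Terms categorised "Unused" carry a weight in
#' burden scores but are excluded from category analyses.
#'
#' @inheritParams functional_weight
#' @return Character vector of categories.
#' @export
variant_category <- function(consequence, table = annotation_weights()) {
  table$category[.match_consequence(consequence, table)]
}

#' Rarity weight from minor allele frequency
#'
#' Linear interpolation between the two anchors of the weighting scheme:
#' weight 1 at MAF = 0.01 (the rarity cap for qualifying variants) rising to
#' weight 10 as MAF approaches 0, i.e. `w = 10 - 900 * maf`. Variants with
#' MAF above the cap must be removed by QC before weighting; frequencies
#' outside \[0, 0.01\] are an error here.
#'
#' @param maf Numeric vector of pooled (cases + controls) minor allele
#'   frequencies, each in \[0, 0.01\].
#' @return Numeric vector of weights in \[1, 10\].
#' @examples
#' maf_weight(c(0, 0.005, 0.01))  # 10, 5.5, 1
#' @export
maf_weight <- function(maf) {
  if (any(is.na(maf)) || any(maf < 0) || any(maf > 0.01)) {
    stop("maf must lie in [0, 0.01]; ",
         "variants above the cap must be excluded before weighting")
  }
  10 - 900 * maf
}

#' Combined variant weight
#'
#' Product of the functional weight and the MAF weight, the overall weight a
#' variant contributes per allele to the gene-wise burden score.
#'
#' @param functional Non-negative functional weights (see
#'   [functional_weight()]).
#' @param maf Pooled MAFs in \[0, 0.01\] (see [maf_weight()]).
#' @return Numeric vector of combined weights.
#' @export
combined_weight <- function(functional, maf) {
  if (any(is.na(functional)) || any(functional < 0)) {
    stop("functional weights must be non-negative")
  }
  functional * maf_weight(maf)
}

#' Attach weights and categories to a variant table
#'
#' Convenience wrapper computing, for each variant row, its functional
#' weight, broad category, MAF weight and combined weight.
#'
#' @param variants Data.frame with columns `consequence` and optionally
#'   `polyphen`, `sift` (absent columns are treated as "none").
#' @param maf Pooled minor allele frequency per row, in \[0, 0.01\].
#' @param table Weight table as returned by [annotation_weights()].
#' @return `variants` with added columns `functional_weight`, `category`,
#'   `maf_weight`, `weight`.
#' @export
weight_variants <- function(variants, maf, table = annotation_weights()) {
  stopifnot(is.data.frame(variants), "consequence" %in% names(variants),
            length(maf) == nrow(variants))
  pp <- if ("polyphen" %in% names(variants)) variants$polyphen else "none"
  sf <- if ("sift" %in% names(variants)) variants$sift else "none"
  variants$functional_weight <- functional_weight(variants$consequence, pp, sf,
                                                  table = table)
  variants$category <- variant_category(variants$consequence, table = table)
  variants$maf_weight <- maf_weight(maf)
  variants$weight <- variants$functional_weight * variants$maf_weight
  variants
}
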