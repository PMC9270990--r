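# Plain-text input/output: commented TSVs, cohort export (TSV or VCF) and
# genotype readers.

#' Write a data.frame as a commented TSV
#'
#' Output convention used by every pipeline stage: optional metadata lines
#' starting `"## "`, then a header line starting `"#"`, then tab-separated
#' rows. Diffable and language-neutral.
#'
#' @param x Data.frame.
#' @param path Output path.
#' @param comments Character vector of metadata lines (written as
#'   `"## <line>"`).
#' @export
write_wb_tsv <- function(x, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments) > 0) writeLines(paste0("## ", comments), con)
  writeLines(paste0("#", paste(names(x), collapse = "\t")), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a commented TSV written by [write_wb_tsv()]
#'
#' @param path Input path.
#' @return Data.frame; metadata lines are in `attr(, "comments")`.
#' @export
read_wb_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- grepl("^##", lines)
  header_i <- which(!meta & grepl("^#", lines))[1]
  if (is.na(header_i)) stop("no '#'-prefixed header line in ", path)
  header <- strsplit(sub("^#", "", lines[header_i]), "\t", fixed = TRUE)[[1]]
  body <- lines[-seq_len(header_i)]
  body <- body[!grepl("^#", body)]
  if (length(body) == 0) {
    out <- as.data.frame(stats::setNames(rep(list(character(0)),
                                             length(header)), header))
  } else {
    out <- utils::read.delim(text = body, header = FALSE,
                             col.names = header, na.strings = "NA",
                             stringsAsFactors = FALSE, check.names = FALSE)
  }
  attr(out, "comments") <- sub("^## ?", "", lines[meta])
  out
}

#' Export a simulated cohort to plain-text files
#'
#' Writes, under `dir`: `genotypes.tsv` (subjects x variants allele-count
#' matrix) or `genotypes.vcf` (biallelic GT records, missing as `./.`,
#' males hemizygous on X, 1-based positions), `annotation.tsv` (chrom, pos,
#' ref, alt, gene, consequence, polyphen, sift), `covariates.tsv` (subject,
#' sex, PCs) and `phenotypes.tsv` (subject, phenotype, status). The RNG
#' seed is recorded in each file's metadata comments.
#'
#' @param cohort A `wb_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param format `"tsv"` or `"vcf"` for the genotypes.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  stopifnot(inherits(cohort, "wb_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed_note <- paste("seed:", cohort$config$seed)

  if (format == "tsv") {
    g <- as.data.frame(cohort$genotypes)
    g <- cbind(subject = rownames(cohort$genotypes), g)
    write_wb_tsv(g, file.path(dir, "genotypes.tsv"), comments = seed_note)
  } else {
    write_cohort_vcf(cohort, file.path(dir, "genotypes.vcf"))
  }
  vcols <- c("id", "chrom", "pos", "ref", "alt", "gene", "consequence",
             "polyphen", "sift")
  write_wb_tsv(cohort$variants[vcols], file.path(dir, "annotation.tsv"),
               comments = seed_note)
  cov_cols <- c("subject", "sex",
                grep("^PC", names(cohort$cohort), value = TRUE))
  write_wb_tsv(cohort$cohort[cov_cols], file.path(dir, "covariates.tsv"),
               comments = seed_note)
  ph <- data.frame(subject = cohort$cohort$subject, phenotype = "case",
                   status = cohort$cohort$case, stringsAsFactors = FALSE)
  write_wb_tsv(ph, file.path(dir, "phenotypes.tsv"), comments = seed_note)
  invisible(dir)
}

#' Write simulated genotypes as a minimal VCF
#'
#' Biallelic records with a GT-only FORMAT field; missing genotypes are
#' `./.`; males on the X chromosome are written with haploid genotypes.
#'
#' @param cohort A `wb_cohort`.
#' @param path Output `.vcf` path.
#' @export
write_cohort_vcf <- function(cohort, path) {
  g <- cohort$genotypes
  v <- cohort$variants
  male <- cohort$cohort$sex == 1
  is_x <- v$chrom == "X"
  code <- c("0/0", "0/1", "1/1")
  gt <- matrix(code[g + 1L], nrow = nrow(g))
  gt[is.na(g)] <- "./."
  if (any(is_x) && any(male)) {
    hap <- c("0", "1")
    gx <- g[male, is_x, drop = FALSE]
    hx <- matrix(hap[gx + 1L], nrow = nrow(gx))
    hx[is.na(gx)] <- "."
    gt[male, is_x] <- hx
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##source=wburden simulate_cohort seed=",
                      cohort$config$seed),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", rownames(g)),
                     collapse = "\t")), con)
  body <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
                sep = "\t")
  body <- paste(body, apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Parses biallelic GT records (multiallelics must be pre-split) into the
#' subjects x variants allele-count matrix used throughout the package.
#' Haploid calls (hemizygous males) are stored as 0/1. Requires the vcfR
#' package.
#'
#' @param path Path to a VCF file.
#' @return List: `genotypes` (integer matrix, `NA` = missing) and
#'   `variants` (data.frame id, chrom, pos, ref, alt).
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE))) {
    stop("multiallelic records must be split before reading")
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  count_alt <- function(s) {
    alleles <- strsplit(s, "[/|]")
    vapply(alleles, function(a) {
      if (length(a) == 0 || anyNA(a) || all(a == ".")) return(NA_integer_)
      sum(a == "1")
    }, integer(1))
  }
  counts <- apply(gt, 2, count_alt)
  counts <- matrix(as.integer(counts), nrow = nrow(gt),
                   dimnames = dimnames(gt))
  variants <- data.frame(id = fix$ID, chrom = fix$CHROM,
                         pos = as.integer(fix$POS), ref = fix$REF,
                         alt = fix$ALT, stringsAsFactors = FALSE)
  missing_id <- is.na(variants$id) | variants$id == "."
  variants$id[missing_id] <- paste(variants$chrom, variants$pos,
                                   variants$ref, variants$alt,
                                   sep = ":")[missing_id]
  geno <- t(counts)
  colnames(geno) <- variants$id
  list(genotypes = geno, variants = variants)
}

#' Read an allele-count genotype TSV
#'
#' Inverse of the TSV branch of [write_cohort()]: a commented TSV with a
#' `subject` column followed by one integer column per variant.
#'
#' @param path Path to the TSV.
#' @return Integer matrix, subjects x variants.
#' @export
read_genotypes_tsv <- function(path) {
  tab <- read_wb_tsv(path)
  if (names(tab)[1] != "subject") {
    stop("genotype TSV must start with a 'subject' column")
  }
  g <- as.matrix(tab[-1])
  storage.mode(g) <- "integer"
  rownames(g) <- tab$subject
  g
}
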