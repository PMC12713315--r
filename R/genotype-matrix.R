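#' Genotype matrix container
#'
#' Bundles an additively coded genotype matrix (samples x SNPs, minor-allele
#' copy counts 0/1/2, `NA` = missing) with its variant map and sample
#' metadata.  This is the object every pipeline stage consumes and returns.
#'
#' @param geno integer matrix, samples in rows, SNPs in columns; entries in
#'   \{0, 1, 2, NA\}.  Row names are sample ids, column names SNP ids (both
#'   filled in from `variants`/`samples` when absent).
#' @param variants data frame with one row per SNP: `chr`, `pos` (1-based),
#'   `snp_id`, `allele1` (minor/counted allele), `allele2`.
#' @param samples data frame with one row per sample: `sample_id`, `sex`
#'   (1 = male, 2 = female, NA allowed) and zero or more trait status columns
#'   coded 1 = control, 2 = case, -9 = missing (PLINK convention).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, variants, samples) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (!is.data.frame(variants) || !all(c("chr", "pos", "snp_id", "allele1", "allele2") %in% names(variants)))
    stop("`variants` must be a data frame with chr, pos, snp_id, allele1, allele2", call. = FALSE)
  if (!is.data.frame(samples) || !"sample_id" %in% names(samples))
    stop("`samples` must be a data frame with a sample_id column", call. = FALSE)
  if (nrow(variants) != ncol(geno))
    stop("variant table rows (", nrow(variants), ") != genotype columns (", ncol(geno), ")", call. = FALSE)
  if (nrow(samples) != nrow(geno))
    stop("sample table rows (", nrow(samples), ") != genotype rows (", nrow(geno), ")", call. = FALSE)
  bad <- geno[!is.na(geno)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("genotype codes must be 0, 1, 2 or NA", call. = FALSE)
  if (any(variants$pos <= 0)) stop("variant positions must be positive", call. = FALSE)
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids", call. = FALSE)
  rownames(geno) <- as.character(samples$sample_id)
  colnames(geno) <- as.character(variants$snp_id)
  structure(list(geno = geno, variants = variants, samples = samples),
            class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' @export
print.genotype_matrix <- function(x, ...) {
  traits <- trait_columns(x$samples)
  cat("genotype_matrix: ", nrow(x$geno), " samples x ", ncol(x$geno), " SNPs\n", sep = "")
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing genotype rate: %.4f\n", miss))
  if (length(traits))
    cat("  traits:", paste(traits, collapse = ", "), "\n")
  invisible(x)
}

# trait status columns = everything in the sample table that is not id/sex
trait_columns <- function(samples) {
  setdiff(names(samples), c("sample_id", "sex"))
}

#' Subset a genotype matrix by samples and/or SNPs
#'
#' @param x a `genotype_matrix`
#' @param samples,snps logical/integer/character index into samples / SNPs
#'   (defaults keep everything)
#' @return a `genotype_matrix`
#' @export
subset_genotypes <- function(x, samples = NULL, snps = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  si <- if (is.null(samples)) seq_len(nrow(x$geno)) else samples
  vi <- if (is.null(snps)) seq_len(ncol(x$geno)) else snps
  if (is.character(si)) si <- match(si, x$samples$sample_id)
  if (is.character(vi)) vi <- match(vi, x$variants$snp_id)
  genotype_matrix(x$geno[si, vi, drop = FALSE],
                  x$variants[vi, , drop = FALSE],
                  x$samples[si, , drop = FALSE])
}

#' Extract a binary case/control vector for one trait
#'
#' Converts PLINK-coded status (1 = control, 2 = case, -9 = missing) to a
#' 0/1 integer vector with `NA` for missing.
#'
#' @param x a `genotype_matrix` or a sample data frame
#' @param trait trait column name
#' @return integer vector (0 = control, 1 = case, NA = missing)
#' @export
trait_status <- function(x, trait) {
  samples <- if (inherits(x, "genotype_matrix")) x$samples else x
  if (!trait %in% names(samples))
    stop("trait '", trait, "' not found", call. = FALSE)
  s <- samples[[trait]]
  out <- ifelse(s == 2L, 1L, ifelse(s == 1L, 0L, NA_integer_))
  as.integer(out)
}
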