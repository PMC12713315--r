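#' Annotation harmonization configuration
#'
#' @param palindrome_maf_cutoff MAF at or above which a palindromic
#'   (A/T or C/G) SNP is excluded as strand-ambiguous; inclusive at the
#'   cutoff (default 0.40)
#' @param q_cutoff q-value below which an eQTL record is flagged
#'   significant (default 0.05)
#' @return an `annotation_config`
#' @export
annotation_config <- function(palindrome_maf_cutoff = 0.40, q_cutoff = 0.05) {
  if (palindrome_maf_cutoff <= 0 || palindrome_maf_cutoff >= 1 ||
      q_cutoff <= 0 || q_cutoff >= 1)
    stop("cutoffs must be in (0, 1)", call. = FALSE)
  structure(list(palindrome_maf_cutoff = palindrome_maf_cutoff,
                 q_cutoff = q_cutoff), class = "annotation_config")
}

is_palindromic <- function(a1, a2) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  comp[a1] == a2
}

#' Exclude strand-ambiguous palindromic SNPs
#'
#' A SNP is excluded iff its allele pair is complementary (A/T or C/G)
#' AND its MAF is at or above the cutoff; palindromic SNPs below the
#' cutoff pass through flagged `"palindromic-low-maf"` (no strand
#' flipping is attempted).
#'
#' @param snps data frame with `snp_id`, `allele1`, `allele2`, `maf`
#' @param config an [annotation_config()]
#' @return list: `retained` (data frame with a `flag` column: `"ok"` or
#'   `"palindromic-low-maf"`) and `excluded` (with a `reason` column)
#' @export
filter_palindromic <- function(snps, config = annotation_config()) {
  stopifnot(is.data.frame(snps),
            all(c("snp_id", "allele1", "allele2", "maf") %in% names(snps)))
  if (!all(snps$allele1 %in% c("A", "C", "G", "T")) ||
      !all(snps$allele2 %in% c("A", "C", "G", "T")))
    stop("invalid allele symbol (must be A, C, G or T)", call. = FALSE)
  pal <- is_palindromic(snps$allele1, snps$allele2)
  out <- pal & snps$maf >= config$palindrome_maf_cutoff
  retained <- snps[!out, , drop = FALSE]
  retained$flag <- ifelse(pal[!out], "palindromic-low-maf", "ok")
  excluded <- snps[out, , drop = FALSE]
  excluded$reason <- if (nrow(excluded))
    sprintf("palindromic (%s/%s) with MAF %.3f >= %.2f", excluded$allele1,
            excluded$allele2, excluded$maf, config$palindrome_maf_cutoff)
  else character(0)
  rownames(retained) <- rownames(excluded) <- NULL
  list(retained = retained, excluded = excluded)
}

#' Join selected SNPs onto a user-supplied cis-eQTL table
#'
#' Left join by rsID: every selected SNP appears in the output at least
#' once; SNPs without a record carry empty annotation fields.  Records are
#' flagged significant iff `qval < q_cutoff`.  Duplicate records for one
#' (snp, gene, tissue) key with conflicting content are an error.
#'
#' @param snp_ids character vector of selected SNP rsIDs
#' @param eqtl data frame with at least `snp_id`, `gene_id`, `gene_name`,
#'   `tissue`, `slope`, `slope_se`, `pval_nominal`, `qval`
#' @param config an [annotation_config()]
#' @return data frame: one row per (selected SNP, eQTL record) pair plus
#'   `significant` flag; unmatched SNPs get one all-NA annotation row
#' @export
eqtl_join <- function(snp_ids, eqtl, config = annotation_config()) {
  req <- c("snp_id", "gene_id", "gene_name", "tissue", "slope", "slope_se",
           "pval_nominal", "qval")
  stopifnot(is.data.frame(eqtl), all(req %in% names(eqtl)))
  if (any(eqtl$qval < 0 | eqtl$qval > 1, na.rm = TRUE))
    stop("qval must be in [0, 1]", call. = FALSE)
  key <- paste(eqtl$snp_id, eqtl$gene_id, eqtl$tissue, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    rows <- eqtl[key == dup, req, drop = FALSE]
    if (nrow(unique(rows)) > 1)
      stop("conflicting duplicate eQTL records for key ",
           gsub("\r", "/", dup), call. = FALSE)
    eqtl <- eqtl[!duplicated(key), , drop = FALSE]
  }
  hits <- eqtl[eqtl$snp_id %in% snp_ids, req, drop = FALSE]
  missing_ids <- setdiff(snp_ids, hits$snp_id)
  if (length(missing_ids)) {
    pad <- hits[rep(NA_integer_, length(missing_ids)), , drop = FALSE]
    pad$snp_id <- missing_ids
    hits <- rbind(hits, pad)
  }
  hits <- hits[order(match(hits$snp_id, snp_ids)), , drop = FALSE]
  hits$significant <- !is.na(hits$qval) & hits$qval < config$q_cutoff
  rownames(hits) <- NULL
  hits
}

#' Write an annotation table as TSV
#'
#' @param annotation data frame from [eqtl_join()]
#' @param path output TSV path (GRCh38, 1-based positions noted in header)
#' @return `path` invisibly
#' @export
write_annotation <- function(annotation, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: GRCh38, 1-based; significant = qval < cutoff", con)
  utils::write.table(annotation, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
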