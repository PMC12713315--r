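#' Quality-control thresholds
#'
#' Defaults follow community-standard PLINK practice for array data:
#' sample and SNP call rate >= 0.95, MAF >= 0.05, Hardy-Weinberg exact
#' p >= 1e-6 in controls, per-sample heterozygosity within 3 SD of the
#' cohort mean, and pairwise relatedness below 0.1875 (between 2nd- and
#' 3rd-degree) on a genotype-correlation kinship estimate.
#'
#' @param min_snp_call_rate,min_sample_call_rate call-rate floors in \[0, 1\]
#' @param min_maf minor-allele-frequency floor in \[0, 0.5\]
#' @param min_hwe_p HWE exact-test p-value floor, applied in controls
#' @param het_z_limit heterozygosity |z| ceiling (> 0)
#' @param max_relatedness pairwise kinship ceiling in \[0, 1\]
#' @return a `qc_thresholds` list
#' @export
qc_thresholds <- function(min_snp_call_rate = 0.95, min_sample_call_rate = 0.95,
                          min_maf = 0.05, min_hwe_p = 1e-6, het_z_limit = 3,
                          max_relatedness = 0.1875) {
  props <- c(min_snp_call_rate, min_sample_call_rate, min_maf, min_hwe_p,
             max_relatedness)
  if (any(props < 0 | props > 1)) stop("thresholds must be proportions in [0, 1]", call. = FALSE)
  if (het_z_limit <= 0) stop("het_z_limit must be > 0", call. = FALSE)
  structure(list(min_snp_call_rate = min_snp_call_rate,
                 min_sample_call_rate = min_sample_call_rate,
                 min_maf = min_maf, min_hwe_p = min_hwe_p,
                 het_z_limit = het_z_limit, max_relatedness = max_relatedness),
            class = "qc_thresholds")
}

#' Per-SNP minor-allele frequency
#'
#' Frequency of the less common allele among non-missing calls; `NA` for
#' SNPs with no calls at all (flagged, not an error).
#'
#' @param G a `genotype_matrix` or a plain 0/1/2/NA matrix (SNPs in columns)
#' @return numeric vector in \[0, 0.5\] (or `NA`), one entry per SNP
#' @export
compute_maf <- function(G) {
  geno <- if (inherits(G, "genotype_matrix")) G$geno else as.matrix(G)
  n_called <- colSums(!is.na(geno))
  alt <- colSums(geno, na.rm = TRUE) / (2 * n_called)
  alt[n_called == 0] <- NA_real_
  pmin(alt, 1 - alt)
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test given the allele counts: the p-value is the total
#' probability, under HWE, of heterozygote counts whose conditional
#' probability does not exceed that of the observed count (the support is
#' parity-constrained by the minor-allele count).  Computed by the standard
#' recurrence over the heterozygote support.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, not all zero)
#' @return two-sided exact p-value in (0, 1\]
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers", call. = FALSE)
  n <- sum(counts)
  if (n == 0) stop("all-zero genotype table: HWE test undefined", call. = FALSE)
  n_rare <- 2 * min(n_AA, n_aa) + n_Aa   # minor allele count
  if (n_rare == 0) return(1.0)           # monomorphic: single outcome
  # heterozygote support: same parity as n_rare, from n_rare mod 2 (or the
  # floor forced by the common-allele count) up to min(n_rare, 2n - n_rare)
  het_max <- min(n_rare, 2L * n - n_rare)  # n_rare <= n always, so = n_rare
  het_min <- n_rare %% 2L
  support <- seq.int(het_min, het_max, by = 2L)
  # unnormalized probabilities via the recurrence
  # P(het+2)/P(het) = 4 * n_hom_rare * n_hom_common / ((het+2) * (het+1))
  probs <- numeric(length(support))
  mid <- which.min(abs(support - n_rare * (2 * n - n_rare) / (2 * n))) # start near mode
  probs[mid] <- 1
  if (mid < length(support)) {
    for (k in mid:(length(support) - 1)) {
      het <- support[k]
      hr <- (n_rare - het) / 2; hc <- n - het - hr
      probs[k + 1] <- probs[k] * 4 * hr * hc / ((het + 2) * (het + 1))
    }
  }
  if (mid > 1) {
    for (k in mid:2) {
      het <- support[k]
      hr <- (n_rare - het) / 2; hc <- n - het - hr
      probs[k - 1] <- probs[k] * het * (het - 1) / (4 * (hr + 1) * (hc + 1))
    }
  }
  probs <- probs / sum(probs)
  obs <- which(support == n_Aa)
  if (length(obs) != 1) stop("observed heterozygote count off-support", call. = FALSE)
  p <- sum(probs[probs <= probs[obs] * (1 + 1e-12)])
  min(p, 1.0)
}

# per-sample heterozygosity rate (het calls / non-missing calls)
sample_het_rate <- function(geno) {
  called <- rowSums(!is.na(geno))
  het <- rowSums(geno == 1L, na.rm = TRUE)
  ifelse(called > 0, het / called, NA_real_)
}

# genotype-correlation kinship (GCTA-style, IBS-derived): mean over SNPs of
# (g_i - 2p)(g_j - 2p) / (2p(1-p)), missing handled pairwise
relatedness_matrix <- function(geno) {
  p <- colSums(geno, na.rm = TRUE) / (2 * colSums(!is.na(geno)))
  keep <- !is.na(p) & p > 0 & p < 1
  geno <- geno[, keep, drop = FALSE]; p <- p[keep]
  z <- sweep(geno, 2, 2 * p, `-`)
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), `/`)
  obs <- !is.na(z)
  z[!obs] <- 0
  num <- tcrossprod(z)
  den <- tcrossprod(obs * 1)
  k <- num / pmax(den, 1)
  k / 2   # scale so full sibs ~ 0.25, unrelated ~ 0
}

#' Apply standard GWAS quality-control filters
#'
#' Filters run in a fixed order, each on the output of the previous step:
#' sample call rate, SNP call rate, MAF, HWE in controls, heterozygosity
#' outliers, relatedness (greedy removal of one member per flagged pair,
#' preferring the sample in most flagged pairs, ties by sample order).
#'
#' @param G a `genotype_matrix`
#' @param status optional PLINK-coded status vector (1 = control, 2 = case)
#'   aligned to samples, used for the in-controls HWE filter; when `NULL`
#'   the first trait column of the sample table is used, and when no trait
#'   exists HWE is computed on all samples
#' @param thresholds a [qc_thresholds()]
#' @return list with `genotypes` (filtered `genotype_matrix`) and `report`
#'   (`qc_report`: per-step removal counts, in application order)
#' @export
apply_qc <- function(G, status = NULL, thresholds = qc_thresholds()) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(thresholds, "qc_thresholds"))
  if (is.null(status)) {
    traits <- trait_columns(G$samples)
    status <- if (length(traits)) G$samples[[traits[1]]] else rep(1L, nrow(G$geno))
  }
  if (length(status) != nrow(G$geno))
    stop("status length != sample count", call. = FALSE)
  steps <- list()
  log_step <- function(step, axis, removed, cur) {
    steps[[length(steps) + 1]] <<- data.frame(
      step = step, axis = axis, removed = removed,
      remaining_samples = nrow(cur$geno), remaining_snps = ncol(cur$geno),
      stringsAsFactors = FALSE)
  }
  cur <- G
  # 1. sample call rate
  cr <- rowMeans(!is.na(cur$geno))
  keep <- cr >= thresholds$min_sample_call_rate
  status <- status[keep]
  cur <- subset_genotypes(cur, samples = which(keep))
  log_step("sample_call_rate", "sample", sum(!keep), cur)
  if (nrow(cur$geno) == 0) stop("QC removed all samples", call. = FALSE)
  # 2. SNP call rate
  cr <- colMeans(!is.na(cur$geno))
  keep <- cr >= thresholds$min_snp_call_rate
  cur <- subset_genotypes(cur, snps = which(keep))
  log_step("snp_call_rate", "snp", sum(!keep), cur)
  if (ncol(cur$geno) == 0) stop("QC removed all SNPs", call. = FALSE)
  # 3. MAF
  maf <- compute_maf(cur)
  keep <- !is.na(maf) & maf >= thresholds$min_maf
  cur <- subset_genotypes(cur, snps = which(keep))
  log_step("maf", "snp", sum(!keep), cur)
  if (ncol(cur$geno) == 0) stop("QC removed all SNPs", call. = FALSE)
  # 4. HWE in controls
  ctrl <- which(status == 1L)
  hwe_geno <- if (length(ctrl)) cur$geno[ctrl, , drop = FALSE] else cur$geno
  hwe_p <- vapply(seq_len(ncol(hwe_geno)), function(j) {
    g <- hwe_geno[, j]
    g <- g[!is.na(g)]
    if (!length(g)) return(1.0)
    hwe_exact_test(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  }, 0.0)
  keep <- hwe_p >= thresholds$min_hwe_p
  cur <- subset_genotypes(cur, snps = which(keep))
  log_step("hwe_controls", "snp", sum(!keep), cur)
  if (ncol(cur$geno) == 0) stop("QC removed all SNPs", call. = FALSE)
  # 5. heterozygosity outliers
  het <- sample_het_rate(cur$geno)
  s <- stats::sd(het, na.rm = TRUE)
  z <- if (is.na(s) || s == 0) rep(0, length(het)) else (het - mean(het, na.rm = TRUE)) / s
  keep <- abs(z) <= thresholds$het_z_limit
  keep[is.na(keep)] <- FALSE
  status <- status[keep]
  cur <- subset_genotypes(cur, samples = which(keep))
  log_step("heterozygosity", "sample", sum(!keep), cur)
  if (nrow(cur$geno) == 0) stop("QC removed all samples", call. = FALSE)
  # 6. relatedness: greedy removal
  removed_rel <- 0L
  if (nrow(cur$geno) >= 2) {
    k <- relatedness_matrix(cur$geno)
    diag(k) <- 0
    flagged <- k > thresholds$max_relatedness
    drop <- logical(nrow(cur$geno))
    while (any(flagged[!drop, !drop, drop = FALSE])) {
      deg <- rowSums(flagged[, !drop, drop = FALSE] & !drop)
      deg[drop] <- -1
      victim <- which.max(deg)   # ties: first sample in order
      drop[victim] <- TRUE
      flagged[victim, ] <- FALSE
      flagged[, victim] <- FALSE
    }
    removed_rel <- sum(drop)
    status <- status[!drop]
    cur <- subset_genotypes(cur, samples = which(!drop))
  }
  log_step("relatedness", "sample", removed_rel, cur)
  if (nrow(cur$geno) == 0) stop("QC removed all samples", call. = FALSE)
  report <- do.call(rbind, steps)
  class(report) <- c("qc_report", "data.frame")
  attr(report, "input_samples") <- nrow(G$geno)
  attr(report, "input_snps") <- ncol(G$geno)
  list(genotypes = cur, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report (", attr(x, "input_samples"), " samples x ",
      attr(x, "input_snps"), " SNPs in)\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Write a QC report as TSV and JSON
#'
#' @param report a `qc_report`
#' @param prefix output path prefix (writes `<prefix>.tsv`, `<prefix>.json`)
#' @return the prefix, invisibly
#' @export
write_qc_report <- function(report, prefix) {
  utils::write.table(report, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(input_samples = attr(report, "input_samples"),
         input_snps = attr(report, "input_snps"),
         steps = as.data.frame(report)),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
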