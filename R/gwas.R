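#' Covariate model for single-SNP association
#'
#' @param label model label, e.g. `"sex-only"` or `"sex+PC1-3"`
#' @param covariates numeric matrix (samples x covariates) or `NULL`; an
#'   intercept is always added internally and must not be included
#' @return a `covariate_model`
#' @export
covariate_model <- function(label, covariates = NULL) {
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (any(apply(covariates, 2, function(v) all(v == 0))))
      stop("constant-zero covariate column", call. = FALSE)
  }
  structure(list(label = label, covariates = covariates), class = "covariate_model")
}

#' Per-SNP covariate-adjusted logistic association
#'
#' Fits `y ~ genotype + covariates` by maximum-likelihood logistic
#' regression for every SNP, reporting the per-minor-allele-copy log-odds
#' effect with its Wald standard error, z and p-value.  Samples with a
#' missing genotype are dropped per SNP.  Pathological fits are flagged in
#' `status` (`monomorphic`, `separation`, `not_converged`) rather than
#' reported as numbers.
#'
#' @param G a `genotype_matrix`
#' @param y binary 0/1 (or PLINK 1/2) trait vector aligned to samples; must
#'   contain both classes
#' @param model a [covariate_model()]; default sex-only uses the sample
#'   table's sex column (female indicator)
#' @return data frame of class `assoc_result`: `snp_id`, `chr`, `pos`,
#'   `effect`, `se`, `wald_z`, `p_value`, `n_used`, `status`, `model_label`
#' @export
logistic_assoc <- function(G, y, model = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  y <- as.integer(y)
  if (all(y %in% c(1L, 2L))) y <- y - 1L   # PLINK coding
  if (length(y) != nrow(G$geno)) stop("y length != sample count", call. = FALSE)
  keep <- !is.na(y)
  if (length(unique(y[keep])) < 2) stop("y must contain both classes", call. = FALSE)
  if (is.null(model)) {
    sex <- G$samples$sex
    cov <- if (!is.null(sex) && length(unique(sex[!is.na(sex)])) > 1)
      cbind(sex_female = as.numeric(sex == 2)) else NULL
    model <- covariate_model(if (is.null(cov)) "unadjusted" else "sex-only", cov)
  }
  covs <- model$covariates
  if (!is.null(covs) && nrow(covs) != nrow(G$geno))
    stop("covariate rows != sample count", call. = FALSE)
  m <- ncol(G$geno)
  eff <- se <- z <- p <- rep(NA_real_, m)
  n_used <- integer(m)
  status <- rep("ok", m)
  for (j in seq_len(m)) {
    g <- G$geno[, j]
    use <- keep & !is.na(g)
    n_used[j] <- sum(use)
    gu <- g[use]; yu <- y[use]
    if (length(unique(gu)) < 2 || length(unique(yu)) < 2) {
      status[j] <- "monomorphic"
      next
    }
    X <- cbind(`(Intercept)` = 1, genotype = gu,
               if (!is.null(covs)) covs[use, , drop = FALSE])
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(X, yu, family = stats::binomial())),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      status[j] <- "not_converged"
      next
    }
    b <- fit$coefficients["genotype"]
    # Wald SE from the Fisher information at the MLE
    w <- fit$weights
    XtWX <- crossprod(X * sqrt(w))
    cov_b <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(cov_b) || is.na(b)) {
      status[j] <- "not_converged"
      next
    }
    s <- sqrt(cov_b["genotype", "genotype"])
    mu <- fit$fitted.values
    if (abs(b) > 12 || s > 20 || any(mu > 1 - 1e-10) || any(mu < 1e-10)) {
      status[j] <- "separation"
      next
    }
    eff[j] <- b; se[j] <- s; z[j] <- b / s
    p[j] <- 2 * stats::pnorm(-abs(b / s))
    if (p[j] == 0) p[j] <- .Machine$double.xmin
  }
  out <- data.frame(snp_id = G$variants$snp_id, chr = G$variants$chr,
                    pos = G$variants$pos, effect = eff, se = se, wald_z = z,
                    p_value = p, n_used = n_used, status = status,
                    model_label = model$label, stringsAsFactors = FALSE)
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Principal-component covariates from genotypes
#'
#' Missing genotypes are mean-imputed per SNP, columns centred and scaled
#' to unit variance (zero-variance SNPs contribute nothing), and the top
#' `k` left singular vectors scaled by their singular values are returned.
#' Sign convention: the loading with the largest magnitude on each PC is
#' made positive, so results are deterministic across platforms.
#'
#' @param G a `genotype_matrix`
#' @param k number of components, `0 <= k <= min(n_samples - 1, n_snps)`
#' @return numeric matrix (samples x k) with columns `PC1..PCk`; a
#'   zero-column matrix when `k = 0`
#' @export
pca_covariates <- function(G, k) {
  stopifnot(inherits(G, "genotype_matrix"))
  n <- nrow(G$geno); m <- ncol(G$geno)
  if (k < 0 || k > min(n - 1, m))
    stop("k must be in [0, min(n_samples - 1, n_snps)]", call. = FALSE)
  if (k == 0) return(matrix(0, n, 0))
  x <- G$geno
  mu <- colMeans(x, na.rm = TRUE); mu[is.nan(mu)] <- 0
  for (j in which(colSums(is.na(x)) > 0)) x[is.na(x[, j]), j] <- mu[j]
  x <- scale(x)
  x[, attr(x, "scaled:scale") == 0 | is.na(attr(x, "scaled:scale"))] <- 0
  sv <- svd(x, nu = k, nv = k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  for (j in seq_len(k)) {
    i_max <- which.max(abs(sv$v[, j]))
    if (sv$v[i_max, j] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  scores
}

#' Genomic inflation factor and QQ data
#'
#' lambda_GC is the median of the 1-df chi-square quantiles corresponding
#' to the observed p-values, divided by the null median 0.4549364.  QQ
#' pairs compare observed against uniform order statistics on the
#' -log10 scale.
#'
#' @param p_values p-values in (0, 1\]; `NA` entries (flagged fits) are
#'   dropped
#' @return list of class `genomic_inflation`: `lambda_gc`, `n_tests`, `qq`
#'   (data frame `expected`, `observed`)
#' @export
lambda_gc <- function(p_values) {
  p <- p_values[!is.na(p_values)]
  if (!length(p)) stop("no p-values supplied", call. = FALSE)
  if (any(p <= 0 | p > 1)) stop("p-values must be in (0, 1]", call. = FALSE)
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  lam <- stats::median(chisq) / stats::qchisq(0.5, df = 1)
  m <- length(p)
  ps <- sort(p)
  qq <- data.frame(expected = -log10((seq_len(m) - 0.5) / m),
                   observed = -log10(ps))
  structure(list(lambda_gc = lam, n_tests = m, qq = qq),
            class = "genomic_inflation")
}

#' @export
print.genomic_inflation <- function(x, ...) {
  cat(sprintf("genomic inflation: lambda_GC = %.4f over %d tests\n",
              x$lambda_gc, x$n_tests))
  invisible(x)
}

#' Significance thresholds configuration
#'
#' @param stringent_p stringent candidate threshold (default 1e-4)
#' @param lenient_p lenient candidate threshold (default 1e-2)
#' @param alpha family-wise alpha for the Bonferroni cutoff
#' @param fdr_q Benjamini-Hochberg FDR level
#' @return a `threshold_config`
#' @export
threshold_config <- function(stringent_p = 1e-4, lenient_p = 1e-2,
                             alpha = 0.05, fdr_q = 0.05) {
  if (!(stringent_p > 0 && stringent_p < lenient_p && lenient_p < 1))
    stop("need 0 < stringent_p < lenient_p < 1", call. = FALSE)
  structure(list(stringent_p = stringent_p, lenient_p = lenient_p,
                 alpha = alpha, fdr_q = fdr_q), class = "threshold_config")
}

#' Bonferroni cutoff and Benjamini-Hochberg significance mask
#'
#' @param p_values p-values in (0, 1\] (`NA` allowed; `NA` entries are never
#'   significant and do not count toward `m`)
#' @param config a [threshold_config()]
#' @return list: `bonferroni_cutoff` (= alpha / m) and `fdr_significant`
#'   (logical mask aligned to the input, BH step-up at `fdr_q`)
#' @export
multiple_testing <- function(p_values, config = threshold_config()) {
  ok <- !is.na(p_values)
  if (!any(ok)) stop("no p-values supplied", call. = FALSE)
  if (any(p_values[ok] <= 0 | p_values[ok] > 1))
    stop("p-values must be in (0, 1]", call. = FALSE)
  m <- sum(ok)
  adj <- rep(NA_real_, length(p_values))
  adj[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  mask <- !is.na(adj) & adj <= config$fdr_q
  list(bonferroni_cutoff = config$alpha / m, fdr_significant = mask)
}

#' Per-trait candidate SNP sets and their union
#'
#' @param assoc_list named list of `assoc_result` data frames, one per trait
#' @param threshold candidate p-value threshold (SNPs with `p < threshold`)
#' @return list of class `candidate_sets`: `per_trait` (named list of SNP id
#'   vectors), `union` (deduplicated), `sizes` (per-trait and union counts)
#' @export
candidate_union <- function(assoc_list, threshold) {
  stopifnot(is.list(assoc_list), length(assoc_list) >= 1)
  per_trait <- lapply(assoc_list, function(a) {
    sel <- !is.na(a$p_value) & a$p_value < threshold
    a$snp_id[sel]
  })
  u <- unique(unlist(per_trait, use.names = FALSE))
  sizes <- c(vapply(per_trait, length, 0L), union = length(u))
  structure(list(per_trait = per_trait, union = u, sizes = sizes,
                 threshold = threshold), class = "candidate_sets")
}

#' @export
print.candidate_sets <- function(x, ...) {
  cat("candidate SNP sets at p <", format(x$threshold), "\n")
  print(x$sizes)
  invisible(x)
}

#' Write association results and genomic-control report
#'
#' @param assoc an `assoc_result` data frame
#' @param path TSV output path (a coding header line is prepended)
#' @return `path` invisibly
#' @export
write_assoc <- function(assoc, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# effect = log-odds per minor-allele copy; pos 1-based", con)
  utils::write.table(assoc, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param inflation a `genomic_inflation` object
#' @param path JSON output path
#' @rdname write_assoc
#' @export
write_inflation <- function(inflation, path) {
  jsonlite::write_json(list(lambda_gc = inflation$lambda_gc,
                            n_tests = inflation$n_tests,
                            qq = inflation$qq),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
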