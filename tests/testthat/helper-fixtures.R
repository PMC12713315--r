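# small in-code fixtures shared across test files

# genotype_matrix from a plain matrix, minimal metadata
gm_from_matrix <- function(m, sex = NULL, traits = NULL) {
  m <- as.matrix(m)
  n <- nrow(m); p <- ncol(m)
  variants <- data.frame(chr = 1L, pos = seq_len(p) * 100L,
                         snp_id = sprintf("rs%04d", seq_len(p)),
                         allele1 = "A", allele2 = "G",
                         stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = sprintf("s%03d", seq_len(n)),
                        sex = if (is.null(sex)) rep(1L, n) else sex,
                        stringsAsFactors = FALSE)
  if (!is.null(traits)) for (nm in names(traits)) samples[[nm]] <- traits[[nm]]
  genotype_matrix(m, variants, samples)
}

# independent closed-form enumeration oracle for the HWE exact test
hwe_enum_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * min(n_AA, n_aa) + n_Aa
  if (nA == 0) return(1.0)
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  lp <- vapply(hets, function(h) {
    hr <- (nA - h) / 2; hc <- n - h - hr
    lfactorial(n) - lfactorial(hr) - lfactorial(h) - lfactorial(hc) +
      h * log(2) - lchoose(2 * n, nA)
  }, 0.0)
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  obs <- pr[hets == n_Aa]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# brute-force O(n^2) pairwise AUC oracle
auc_pairwise_oracle <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# exhaustive subset-search oracle (all subsets incl. empty) for <= ~12 features
exhaustive_best_score <- function(X, y, clf) {
  p <- ncol(X)
  best <- -Inf
  for (m in 0:(2^p - 1)) {
    idx <- which(bitwAnd(m, 2^(seq_len(p) - 1)) > 0)
    s <- loocv_accuracy(X[, idx, drop = FALSE], y, clf)
    if (s > best) best <- s
  }
  best
}
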