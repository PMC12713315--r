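test_that("compute_maf counts alleles, excludes missing, flags empty SNPs", {
  m <- cbind(c(0L, 0L, 1L, 2L),      # alt freq 3/8
             c(0L, 0L, 0L, 0L),      # monomorphic
             c(0L, NA, 2L, NA),      # missing excluded: alt 2/4
             c(NA, NA, NA, NA))      # undefined
  maf <- compute_maf(m)
  expect_equal(maf[1], 0.375)
  expect_equal(maf[2], 0)
  expect_equal(maf[3], 0.5)
  expect_true(is.na(maf[4]))
})

test_that("compute_maf agrees with brute-force allele counting on random matrices", {
  set.seed(42)
  for (rep in 1:20) {
    m <- matrix(sample(c(0:2, NA), 60, replace = TRUE), 10, 6)
    expected <- apply(m, 2, function(g) {
      g <- g[!is.na(g)]
      if (!length(g)) return(NA_real_)
      f <- sum(g) / (2 * length(g))
      min(f, 1 - f)
    })
    expect_equal(compute_maf(m), expected)
  }
})

test_that("HWE exact test matches the enumeration oracle on key tables", {
  expect_equal(hwe_exact_test(0, 0, 50), 1.0)
  expect_equal(hwe_exact_test(1, 2, 1), hwe_enum_oracle(1, 2, 1))
  p <- hwe_exact_test(50, 0, 50)
  expect_equal(p, hwe_enum_oracle(50, 0, 50))
  expect_lt(p, 1e-6)
  expect_error(hwe_exact_test(0, 0, 0), "all-zero")
})

test_that("clean data passes QC untouched and single violations are localized", {
  set.seed(11)
  # enough SNPs that the kinship estimate is tight and no pair is falsely flagged
  G <- simulate_genotypes(sim_config(n_samples = 60, n_snps = 500,
                                     maf_low = 0.2, maf_high = 0.5, seed = 31))
  # het_z_limit 4: the default |z| <= 3 trims ~0.3% of genuinely clean
  # samples (distribution tails), which is correct but not "untouched"
  thr <- qc_thresholds(het_z_limit = 4)
  res <- apply_qc(G, status = rep(1L, 60), thresholds = thr)
  expect_equal(sum(res$report$removed), 0)
  expect_identical(res$genotypes$geno, G$geno)

  # one SNP with call rate 0.90 under min 0.95
  G2 <- G
  G2$geno[1:6, 3] <- NA_integer_
  res2 <- apply_qc(G2, status = rep(1L, 60), thresholds = thr)
  rep2 <- res2$report
  expect_equal(rep2$removed[rep2$step == "snp_call_rate"], 1)
  expect_false("rs000003" %in% res2$genotypes$variants$snp_id)
  expect_equal(sum(rep2$removed), 1)
})

test_that("HWE filter removes a planted heterozygote-deficit SNP in controls", {
  set.seed(12)
  G <- simulate_genotypes(sim_config(n_samples = 100, n_snps = 300,
                                     maf_low = 0.2, maf_high = 0.5, seed = 32))
  G$geno[, 5] <- c(rep(0L, 50), rep(2L, 50))   # (50, 0, 50): p < 1e-6
  res <- apply_qc(G, status = rep(1L, 100))
  expect_equal(res$report$removed[res$report$step == "hwe_controls"], 1)
  expect_false("rs000005" %in% res$genotypes$variants$snp_id)
})

test_that("apply_qc is idempotent on its own output", {
  set.seed(13)
  G <- simulate_genotypes(sim_config(n_samples = 80, n_snps = 400,
                                     maf_low = 0.05, maf_high = 0.5,
                                     missing_rate = 0.03, seed = 33))
  thr <- qc_thresholds(het_z_limit = 4)
  first <- apply_qc(G, status = rep(1L, 80), thresholds = thr)
  second <- apply_qc(first$genotypes, status = rep(1L, nrow(first$genotypes$geno)),
                     thresholds = thr)
  expect_equal(sum(second$report$removed), 0)
})

test_that("relatedness filter removes one member of a duplicated sample pair", {
  set.seed(14)
  G <- simulate_genotypes(sim_config(n_samples = 50, n_snps = 600,
                                     maf_low = 0.2, maf_high = 0.5, seed = 34))
  G$geno[2, ] <- G$geno[1, ]   # identical twins
  res <- apply_qc(G, status = rep(1L, 50))
  expect_equal(res$report$removed[res$report$step == "relatedness"], 1)
  expect_equal(nrow(res$genotypes$geno), 49)
})

test_that("QC that would remove everything raises an explicit error", {
  G <- gm_from_matrix(matrix(NA_integer_, 4, 3))
  expect_error(apply_qc(G, status = rep(1L, 4)), "all samples")
})
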