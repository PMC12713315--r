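test_that("unadjusted logistic effect equals the closed-form 2x2 log odds ratio", {
  g <- c(rep(1L, 10), rep(0L, 40), rep(1L, 5), rep(0L, 45))
  y <- c(rep(1L, 50), rep(0L, 50))
  G <- gm_from_matrix(matrix(g, ncol = 1))
  a <- logistic_assoc(G, y, covariate_model("unadjusted"))
  expect_equal(a$status, "ok")
  expect_lt(abs(a$effect - log((10 * 45) / (40 * 5))), 1e-4)
})

test_that("monomorphic and single-class inputs are flagged or rejected", {
  G <- gm_from_matrix(cbind(rep(1L, 20), rep(0L, 20)))
  y <- rep(c(0L, 1L), 10)
  a <- logistic_assoc(G, y, covariate_model("unadjusted"))
  expect_equal(a$status[2], "monomorphic")
  expect_true(is.na(a$p_value[2]))
  expect_error(logistic_assoc(G, rep(1L, 20)), "both classes")
})

test_that("perfectly separating SNPs are flagged, not reported as numbers", {
  g <- c(rep(2L, 10), rep(0L, 10))
  y <- c(rep(1L, 10), rep(0L, 10))
  a <- logistic_assoc(gm_from_matrix(matrix(g, ncol = 1)), y,
                      covariate_model("unadjusted"))
  expect_true(a$status %in% c("separation", "not_converged"))
  expect_true(is.na(a$p_value))
})

test_that("null simulation p-values are uniform and lambda_GC is calibrated", {
  G <- simulate_genotypes(sim_config(n_samples = 500, n_snps = 1000, seed = 41))
  set.seed(42)
  y <- rbinom(500, 1, 0.5)
  a <- logistic_assoc(G, y)   # sex-only model
  p <- a$p_value[a$status == "ok"]
  expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.01)
  lam <- lambda_gc(p)$lambda_gc
  expect_gt(lam, 0.85); expect_lt(lam, 1.15)
})

test_that("a planted OR-3 SNP at MAF 0.3 reaches p < 1e-4 in most replicates", {
  hits <- 0L
  for (s in 1:20) {
    G <- simulate_genotypes(sim_config(n_samples = 500, n_snps = 5,
                                       maf_low = 0.3, maf_high = 0.3, seed = 100 + s))
    ph <- simulate_phenotypes(
      G, list(t = trait_model(intercept = -log(3) * 0.6,
                              additive_effects = c(rs000003 = log(3)))),
      seed = 200 + s)
    y <- trait_status(ph$samples, "t")
    a <- logistic_assoc(G, y)
    if (!is.na(a$p_value[3]) && a$p_value[3] < 1e-4) hits <- hits + 1L
  }
  expect_gte(hits / 20, 0.8)
})

test_that("lambda_gc matches quantile arithmetic and rejects bad input", {
  expect_equal(lambda_gc(rep(0.5, 100))$lambda_gc, 1.0)
  expect_equal(lambda_gc(rep(0.1, 10))$lambda_gc,
               qchisq(0.9, df = 1) / qchisq(0.5, df = 1), tolerance = 1e-10)
  expect_lt(abs(lambda_gc(rep(0.1, 10))$lambda_gc - 5.947), 0.001)
  set.seed(7)
  lam <- lambda_gc(runif(10000))$lambda_gc
  expect_gt(lam, 0.9); expect_lt(lam, 1.1)
  expect_error(lambda_gc(numeric(0)), "no p-values")
  expect_error(lambda_gc(c(0.5, 0)), "in \\(0, 1\\]")
  qq <- lambda_gc(c(0.2, 0.8, 0.5))$qq
  expect_false(is.unsorted(rev(qq$expected)))
  expect_equal(nrow(qq), 3)
})

test_that("multiple testing gives the Bonferroni cutoff and BH step-up mask", {
  mt <- multiple_testing(runif(20, 0.5, 1), threshold_config(alpha = 0.05))
  expect_equal(mt$bonferroni_cutoff, 0.05 / 20)
  # hand-executed BH at q = 0.05: all four pass (max i with p_i <= i*q/4 is 4)
  mt2 <- multiple_testing(c(0.01, 0.02, 0.03, 0.04))
  expect_true(all(mt2$fdr_significant))
  mt3 <- multiple_testing(0.9)
  expect_equal(mt3$bonferroni_cutoff, 0.05)
  expect_false(any(mt3$fdr_significant))
})

test_that("PCA covariates are orthogonal, deterministic in sign, separate populations", {
  G <- simulate_genotypes(sim_config(n_samples = 100, n_snps = 200, seed = 43))
  expect_equal(ncol(pca_covariates(G, 0)), 0)
  expect_error(pca_covariates(G, 150), "k must be")
  pc <- pca_covariates(G, 4)
  gram <- crossprod(pc)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-6)
  # two planted subpopulations with divergent allele frequencies
  g1 <- simulate_genotypes(sim_config(n_samples = 60, n_snps = 150,
                                      maf_low = 0.1, maf_high = 0.2, seed = 44))
  g2 <- simulate_genotypes(sim_config(n_samples = 60, n_snps = 150,
                                      maf_low = 0.35, maf_high = 0.5, seed = 45))
  gg <- gm_from_matrix(rbind(g1$geno, g2$geno))
  pop <- rep(0:1, each = 60)
  pc1 <- pca_covariates(gg, 1)[, 1]
  expect_gt(abs(cor(pc1, pop)), 0.9)
})

test_that("candidate sets and their union behave as set algebra", {
  mk <- function(ids, ps) {
    a <- data.frame(snp_id = ids, p_value = ps, stringsAsFactors = FALSE)
    class(a) <- c("assoc_result", "data.frame"); a
  }
  cs <- candidate_union(list(t1 = mk(c("a", "b", "x"), c(1e-5, 1e-5, 0.5)),
                             t2 = mk(c("b", "c", "x"), c(1e-5, 1e-5, 0.5)),
                             t3 = mk(c("d", "x", "y"), c(1e-5, 0.5, 0.5))),
                        threshold = 1e-4)
  expect_equal(sort(cs$union), c("a", "b", "c", "d"))
  expect_equal(unname(cs$sizes["union"]), 4L)
  all_in <- candidate_union(list(t = mk(c("a", "b"), c(0.2, 0.9))), threshold = 1.0)
  expect_equal(sort(all_in$union), c("a", "b"))
})

test_that("union reproduces the 10 + 27 + 20 -> 52 overlap pattern", {
  # per-trait sizes 10, 27, 20 with exactly 5 duplicate memberships
  ids <- sprintf("s%02d", 1:52)
  t1 <- ids[1:10]                  # 10
  t2 <- c(ids[8:10], ids[11:34])   # 27, 3 shared with t1
  t3 <- c(ids[33:34], ids[35:52])  # 20, 2 shared with t2
  mk <- function(sel) {
    a <- data.frame(snp_id = sel, p_value = rep(1e-5, length(sel)),
                    stringsAsFactors = FALSE)
    class(a) <- c("assoc_result", "data.frame"); a
  }
  cs <- candidate_union(list(dm = mk(t1), eye = mk(t2), htn = mk(t3)), 1e-4)
  expect_equal(unname(cs$sizes), c(10L, 27L, 20L, 52L))
})
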