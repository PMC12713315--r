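test_that("invalid simulation configs are rejected", {
  expect_error(sim_config(n_samples = 0), "dimensions")
  expect_error(sim_config(maf_low = 0, maf_high = 0), "maf_low")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(ld_rho = 1), "ld_rho")
})

test_that("simulated allele frequencies match their targets within binomial error", {
  G <- simulate_genotypes(sim_config(n_samples = 2000, n_snps = 1,
                                     maf_low = 0.3, maf_high = 0.3, seed = 7))
  fhat <- mean(G$geno[, 1]) / 2
  tol <- 3 * sqrt(0.3 * 0.7 / (2 * 2000))
  expect_lt(abs(fhat - 0.3), tol)
})

test_that("simulated genotypes satisfy HWE marginally", {
  G <- simulate_genotypes(sim_config(n_samples = 500, n_snps = 1000,
                                     maf_low = 0.1, maf_high = 0.5, seed = 21))
  pvals <- vapply(seq_len(1000), function(j) {
    g <- G$geno[, j]
    hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  }, 0.0)
  expect_gte(mean(pvals >= 0.05), 0.93)
})

test_that("LD blocks induce positive adjacent-SNP correlation, independent SNPs none", {
  G <- simulate_genotypes(sim_config(n_samples = 3000, n_snps = 40,
                                     ld_block_size = 4, ld_rho = 0.8, seed = 3))
  within <- cor(G$geno[, 1], G$geno[, 2])
  across <- cor(G$geno[, 4], G$geno[, 5])  # block boundary
  expect_gt(within, 0.3)
  expect_lt(abs(across), 0.08)
})

test_that("genotype simulation is reproducible and missingness is honoured", {
  cfg <- sim_config(n_samples = 100, n_snps = 50, missing_rate = 0.1, seed = 5)
  G1 <- simulate_genotypes(cfg)
  G2 <- simulate_genotypes(cfg)
  expect_identical(G1$geno, G2$geno)
  expect_identical(G1$variants, G2$variants)
  expect_lt(abs(mean(is.na(G1$geno)) - 0.1), 0.02)
})

test_that("null trait model gives 50% prevalence and planted effect is recoverable", {
  G <- simulate_genotypes(sim_config(n_samples = 5000, n_snps = 5,
                                     maf_low = 0.3, maf_high = 0.3, seed = 13))
  # symmetric null
  ph0 <- simulate_phenotypes(G, list(t = trait_model()), seed = 1)
  prev <- mean(ph0$samples$t == 2)
  expect_lt(abs(prev - 0.5), 3 * sqrt(0.25 / 5000))
  # single additive effect beta = ln 2, recovered by logistic refit
  ph1 <- simulate_phenotypes(
    G, list(t = trait_model(intercept = -0.5,
                            additive_effects = c(rs000002 = log(2)))), seed = 2)
  y <- as.integer(ph1$samples$t == 2)
  fit <- glm(y ~ G$geno[, 2], family = binomial())
  expect_lt(abs(unname(coef(fit)[2]) - log(2)), 0.15)
  expect_identical(ph1$ground_truth$causal_snp_ids, "rs000002")
})

test_that("traits with no shared liability or causal SNPs are independent", {
  G <- simulate_genotypes(sim_config(n_samples = 5000, n_snps = 10, seed = 17))
  ph <- simulate_phenotypes(G, list(a = trait_model(), b = trait_model()), seed = 3)
  r <- cor(as.integer(ph$samples$a == 2), as.integer(ph$samples$b == 2))
  expect_lt(abs(r), 0.05)
})

test_that("shared liability induces positive trait correlation", {
  G <- simulate_genotypes(sim_config(n_samples = 5000, n_snps = 10, seed = 19))
  ph <- simulate_phenotypes(G, list(a = trait_model(trait_correlation = 0.9),
                                    b = trait_model(trait_correlation = 0.9)),
                            seed = 4)
  r <- cor(as.integer(ph$samples$a == 2), as.integer(ph$samples$b == 2))
  expect_gt(r, 0.1)
})

test_that("interaction terms require valid distinct SNP pairs", {
  G <- simulate_genotypes(sim_config(n_samples = 50, n_snps = 5, seed = 2))
  expect_error(trait_model(interaction_effects = data.frame(
    snp1 = "rs000001", snp2 = "rs000001", beta = 1)), "not allowed")
  bad <- trait_model(interaction_effects = data.frame(
    snp1 = "rs000001", snp2 = "rs999999", beta = 1))
  expect_error(simulate_phenotypes(G, list(t = bad), seed = 1), "unknown SNP")
})

test_that("intercept tuning hits a target prevalence and resampling hits exact counts", {
  G <- simulate_genotypes(sim_config(n_samples = 4000, n_snps = 5, seed = 23))
  mod <- trait_model(sex_beta = 0.3, additive_effects = c(rs000001 = 0.8))
  a <- intercept_for_prevalence(mod, G, 0.25)
  mod$intercept <- a
  ph <- simulate_phenotypes(G, list(t = mod), seed = 5)
  expect_lt(abs(mean(ph$samples$t == 2) - 0.25), 0.03)
  G$samples <- ph$samples
  G80 <- resample_to_counts(G, "t", n_case = 80, n_control = 16, seed = 6)
  expect_equal(as.integer(table(G80$samples$t)[c("2", "1")]), c(80L, 16L))
})

test_that("visit simulation plants lift and preserves marginal prevalence", {
  # lift * P(D) must stay <= 1 for the marginal of C to be preservable
  prevs <- c(D250 = 0.1, C401 = 0.05, X366 = 0.1)
  planted <- data.frame(antecedent = "D250", consequent = "C401", lift = 8)
  v <- simulate_visits(visit_sim_config(10000, prevs, planted, seed = 9))
  rs <- rule_stats(v, "D250", "C401")
  expect_lt(abs(rs$lift - 8), 1.0)
  # marginals preserved despite the planted lift
  np <- attr(v, "n_patients")
  for (code in names(prevs)) {
    phat <- length(unique(v$patient_id[v$icd9_code == code])) / np
    expect_lt(abs(phat - prevs[[code]]), 3 * sqrt(prevs[[code]] / np) + 0.01)
  }
  # lift 1 = independence
  v1 <- simulate_visits(visit_sim_config(
    10000, prevs, data.frame(antecedent = "D250", consequent = "C401", lift = 1),
    seed = 10))
  expect_lt(abs(rule_stats(v1, "D250", "C401")$lift - 1), 0.2)
})

test_that("impossible planted lifts and empty cohorts are handled", {
  prevs <- c(D = 0.2, C = 0.3)
  expect_error(visit_sim_config(100, prevs,
    data.frame(antecedent = "D", consequent = "C", lift = 5)), "> 1")
  v0 <- simulate_visits(visit_sim_config(0, prevs, seed = 1))
  expect_equal(nrow(v0), 0)
  expect_equal(attr(v0, "n_patients"), 0L)
})
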