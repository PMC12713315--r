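visits_from_flags <- function(D, C, extra = NULL) {
  n <- length(D)
  ids <- sprintf("p%04d", seq_len(n))
  df <- rbind(
    data.frame(patient_id = ids[D], icd9_code = "D", stringsAsFactors = FALSE),
    data.frame(patient_id = ids[C], icd9_code = "C", stringsAsFactors = FALSE),
    extra)
  attr(df, "n_patients") <- n
  df
}

test_that("rule statistics follow their definitions", {
  # n_total 100, n_D 20, n_C 10, n_both 5
  D <- c(rep(TRUE, 20), rep(FALSE, 80))
  C <- c(rep(TRUE, 5), rep(FALSE, 15), rep(TRUE, 5), rep(FALSE, 75))
  rs <- rule_stats(visits_from_flags(D, C), "D", "C")
  expect_equal(rs$confidence, 0.25)
  expect_equal(rs$lift, 2.5)
  expect_equal(rs$support, 0.05)
  expect_equal(rs$n_both, 5)
})

test_that("chi-square equals the Pearson statistic without correction", {
  # 2x2 [[20,30],[10,40]]
  D <- c(rep(TRUE, 50), rep(FALSE, 50))
  C <- c(rep(TRUE, 20), rep(FALSE, 30), rep(TRUE, 10), rep(FALSE, 40))
  rs <- rule_stats(visits_from_flags(D, C), "D", "C")
  expect_equal(rs$chi2, 100 * (20 * 40 - 30 * 10)^2 / (50 * 50 * 30 * 70))
  expect_lt(abs(rs$chi2 - 4.762), 0.001)
  ref <- suppressWarnings(chisq.test(matrix(c(20, 10, 30, 40), 2), correct = FALSE))
  expect_equal(rs$chi2, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(rs$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("chi-square matches stats::chisq.test on many random tables", {
  set.seed(99)
  for (i in 1:200) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    n <- sum(tab)
    D <- rep(c(TRUE, TRUE, FALSE, FALSE), times = as.vector(t(tab)))
    C <- rep(c(TRUE, FALSE, TRUE, FALSE), times = as.vector(t(tab)))
    rs <- rule_stats(visits_from_flags(D, C), "D", "C")
    ref <- suppressWarnings(chisq.test(table(D, C), correct = FALSE))
    expect_equal(rs$chi2, unname(ref$statistic), tolerance = 1e-8)
    # identity: lift * P(C) = confidence
    expect_equal(rs$lift * rs$n_C / rs$n_total, rs$confidence, tolerance = 1e-12)
  }
})

test_that("perfect nesting gives confidence 1 and lift 1/P(C)", {
  D <- c(rep(TRUE, 30), rep(FALSE, 70))
  rs <- rule_stats(visits_from_flags(D, D), "D", "C")
  expect_equal(rs$confidence, 1)
  expect_equal(rs$lift, 1 / 0.3)
})

test_that("duplicated visit records do not change any statistic", {
  D <- c(rep(TRUE, 20), rep(FALSE, 60))
  C <- c(rep(TRUE, 10), rep(FALSE, 30), rep(TRUE, 10), rep(FALSE, 30))
  v <- visits_from_flags(D, C)
  v2 <- rbind(v, v[rep(1:5, 3), ])
  attr(v2, "n_patients") <- attr(v, "n_patients")
  expect_equal(rule_stats(v2, "D", "C"), rule_stats(v, "D", "C"))
})

test_that("zero margins yield an undefined flag, not an exception", {
  # D present in every patient: the not-D margin is zero
  all_d <- visits_from_flags(rep(TRUE, 10), c(rep(TRUE, 5), rep(FALSE, 5)))
  rs <- rule_stats(all_d, "D", "C")
  expect_false(rs$defined)
  expect_true(is.na(rs$chi2))
  expect_true(is.na(rs$lift))
})

test_that("mine_rules ranks by lift, flags significance, and exports edges", {
  prevs <- c(D250 = 0.1, C401 = 0.2, C362 = 0.05, C366 = 0.1)
  planted <- data.frame(antecedent = c("D250", "D250"),
                        consequent = c("C362", "C401"),
                        lift = c(8, 2))
  v <- simulate_visits(visit_sim_config(10000, prevs, planted, seed = 77))
  rules <- mine_rules(v, "D250", min_support = 0.001)
  expect_equal(rules$rules$consequent[1], "C362")
  expect_true(rules$rules$significant[1])
  expect_gt(rules$rules$lift[1], 5)
  expect_identical(names(rules$edges), c("source", "target", "weight", "n"))
  # identity holds on every mined rule
  with(rules$rules, expect_equal(lift * n_C / n_total, confidence, tolerance = 1e-12))
})

test_that("independent codes give near-1 lifts and mostly non-significant rules", {
  prevs <- setNames(rep(0.1, 12), sprintf("C%03d", 1:12))
  v <- simulate_visits(visit_sim_config(10000, prevs, seed = 78))
  rules <- mine_rules(v, "C001")
  expect_true(all(abs(rules$rules$lift - 1) < 0.2))
  expect_gte(mean(!rules$rules$significant), 0.8)
})

test_that("empty visit tables mine to empty rule sets; absent anchors error", {
  empty <- data.frame(patient_id = character(0), icd9_code = character(0))
  expect_equal(nrow(mine_rules(empty, "D250")$rules), 0)
  v <- data.frame(patient_id = "p1", icd9_code = "C100")
  expect_error(mine_rules(v, "D250"), "anchor")
})
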