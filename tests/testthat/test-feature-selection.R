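test_that("LOOCV of the zero rule equals the majority-class fraction (unbalanced)", {
  X <- matrix(0, 96, 1)
  expect_equal(loocv_accuracy(X, c(rep(1, 46), rep(0, 50)),
                              classifier_spec("zero_rule")), 50 / 96)
  expect_error(loocv_accuracy(X, rep(1, 96), classifier_spec("zero_rule")),
               "both classes")
})

test_that("a label-identical feature gives 100% LOOCV accuracy with 1-NN", {
  y <- rep(0:1, 25)
  X <- matrix(as.numeric(y), ncol = 1)
  expect_equal(loocv_accuracy(X, y, classifier_spec("knn", k = 1)), 1.0)
})

test_that("the 1-NN fast path agrees with the explicit train/predict loop", {
  set.seed(51)
  for (i in 1:5) {
    X <- matrix(rnorm(40 * 3), 40, 3)   # continuous: no distance ties
    y <- rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) next
    fast <- loocv_accuracy(X, y, classifier_spec("knn", k = 1))
    slow <- mean(vapply(1:40, function(i) {
      m <- fit_classifier(classifier_spec("knn", k = 1), X[-i, , drop = FALSE], y[-i])
      predict(m, X[i, , drop = FALSE], type = "class") == y[i]
    }, NA))
    expect_equal(fast, slow)
  }
})

test_that("best-first search recovers a planted predictive feature among noise", {
  found <- 0L
  for (s in 1:10) {
    set.seed(60 + s)
    n <- 60
    X <- matrix(rnorm(n * 21), n, 21)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- 0:1
    X[, 7] <- y + rnorm(n, 0, 0.15)   # strongly predictive
    res <- best_first_search(X, y, classifier_spec("c45_tree"), search_config())
    if (7 %in% res$features) found <- found + 1L
  }
  expect_gte(found, 9L)
})

test_that("unbounded stale budget equals the exhaustive-search oracle", {
  set.seed(71)
  for (i in 1:3) {
    X <- matrix(rnorm(40 * 8), 40, 8)
    y <- as.integer(X[, 2] + 0.8 * X[, 5] + rnorm(40) > 0)
    if (length(unique(y)) < 2) next
    clf <- classifier_spec("knn", k = 1)
    res <- best_first_search(X, y, clf, search_config(stale_limit = Inf))
    expect_equal(res$score, exhaustive_best_score(X, y, clf))
    expect_equal(res$n_evaluations, 256L)   # all 2^8 subsets visited once
  }
})

test_that("pure noise with the zero-rule metric returns the empty subset", {
  set.seed(81)
  X <- matrix(rnorm(50 * 6), 50, 6)
  y <- c(rep(1L, 20), rep(0L, 30))
  res <- best_first_search(X, y, classifier_spec("zero_rule"), search_config())
  expect_length(res$features, 0)
  expect_equal(res$score, 30 / 50)   # majority fraction
})

test_that("the best-so-far trace is non-decreasing and bookkeeping is consistent", {
  set.seed(82)
  X <- matrix(rnorm(50 * 7), 50, 7)
  y <- as.integer(X[, 1] > 0)
  res <- best_first_search(X, y, classifier_spec("naive_bayes"), search_config())
  expect_false(is.unsorted(res$trace$best_score))
  expect_equal(res$score, max(res$trace$best_score))
  expect_gte(res$n_evaluations, nrow(res$trace))
})

test_that("a single-candidate pool yields the empty set or that feature by score", {
  set.seed(83)
  y <- rep(0:1, each = 25)
  X <- matrix(y + rnorm(50, 0, 0.2), ncol = 1)
  res <- best_first_search(X, y, classifier_spec("knn", k = 1), search_config())
  expect_equal(res$features, 1L)  # informative: must beat the empty baseline
  Xn <- matrix(rnorm(50), ncol = 1)
  resn <- best_first_search(Xn, y, classifier_spec("zero_rule"), search_config())
  expect_length(resn$features, 0)
})

test_that("fix-once selection is deterministic and beats embedded on permuted labels", {
  set.seed(91)
  n <- 40
  X <- matrix(rbinom(n * 30, 2, 0.3), n, 30)
  y <- rep(0:1, each = n / 2)
  cfg <- search_config(stale_limit = 3, screen_top_k = 8)
  clf <- classifier_spec("knn", k = 1)
  r1 <- fixed_subset_workflow(X, y, clf, cfg)
  r2 <- fixed_subset_workflow(X, y, clf, cfg)
  expect_identical(r1$features, r2$features)
  expect_identical(r1$score, r2$score)
  # honest-vs-optimistic gap on label-permuted data (paired over permutations)
  gaps <- vapply(1:5, function(s) {
    set.seed(200 + s)
    yp <- sample(y)
    fx <- fixed_subset_workflow(X, yp, clf, cfg)
    em <- embedded_selection_cv(X, yp, clf, cfg)
    fx$score - em$honest_accuracy
  }, 0.0)
  expect_gt(mean(gaps), 0)
  expect_gte(mean(gaps > 0), 0.8)
})

test_that("embedded per-fold selection recovers a strong planted 2-SNP signal", {
  ok <- 0L
  for (s in 1:5) {
    set.seed(300 + s)
    n <- 30
    X <- matrix(rbinom(n * 10, 2, 0.3), n, 10)
    eta <- -1.5 + 1.6 * X[, 2] + 1.6 * X[, 9]
    y <- rbinom(n, 1, plogis(eta))
    if (length(unique(y)) < 2) next
    em <- embedded_selection_cv(X, y, classifier_spec("naive_bayes"),
                                search_config(stale_limit = 3))
    hit <- vapply(em$per_fold, function(f) any(c(2L, 9L) %in% f$features), NA)
    if (mean(hit) >= 0.8) ok <- ok + 1L
  }
  expect_gte(ok, 4L)
})
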