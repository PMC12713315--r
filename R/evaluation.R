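#' Cross-validation configuration
#'
#' @param k folds (>= 2), default 10
#' @param repeats repetitions (>= 1), default 10 (the 10 x 10 protocol)
#' @param stratified stratify folds by class (fold class proportions match
#'   the data within one sample); always TRUE in this implementation
#' @param seed integer RNG seed
#' @return a `cv_config`
#' @export
cv_config <- function(k = 10, repeats = 10, stratified = TRUE, seed = 1) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (repeats < 1) stop("repeats must be >= 1", call. = FALSE)
  if (!stratified) stop("only stratified CV is implemented", call. = FALSE)
  structure(list(k = as.integer(k), repeats = as.integer(repeats),
                 stratified = TRUE, seed = as.integer(seed)),
            class = "cv_config")
}

#' Bootstrap configuration
#'
#' @param B replicates (>= 1), default 1000
#' @param stratified resample within class so replicate class counts equal
#'   the originals exactly; always TRUE here
#' @param ci_level percentile confidence level in (0, 1), default 0.95
#' @param seed integer RNG seed
#' @return a `bootstrap_config`
#' @export
bootstrap_config <- function(B = 1000, stratified = TRUE, ci_level = 0.95,
                             seed = 1) {
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  if (ci_level <= 0 || ci_level >= 1) stop("ci_level must be in (0, 1)", call. = FALSE)
  if (!stratified) stop("only stratified bootstrap is implemented", call. = FALSE)
  structure(list(B = as.integer(B), stratified = TRUE, ci_level = ci_level,
                 seed = as.integer(seed)), class = "bootstrap_config")
}

eval_result <- function(metric, values, ci_level = 0.95) {
  values <- values[!is.na(values)]
  qs <- stats::quantile(values, c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2),
                        names = FALSE, type = 7)
  structure(list(metric = metric, values = values, mean = mean(values),
                 sd = stats::sd(values), ci_low = qs[1], ci_high = qs[2],
                 ci_level = ci_level), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("%s: %.4f +/- %.4f  (%g%% CI %.4f-%.4f, %d replicates)\n",
              x$metric, x$mean, ifelse(is.na(x$sd), 0, x$sd),
              100 * x$ci_level, x$ci_low, x$ci_high, length(x$values)))
  invisible(x)
}

#' Train a baseline rule classifier
#'
#' Convenience wrapper around the registry for the two fully specified
#' baselines: `zero_rule` always predicts the training-majority class
#' (ties go to the control class); `one_rule` picks the single feature
#' whose per-value majority rule minimises training error, ties broken by
#' feature order.
#'
#' @param name `"zero_rule"` or `"one_rule"`
#' @param X feature matrix
#' @param y binary 0/1 labels
#' @return a fitted `gf_model`
#' @export
train_baseline <- function(name, X, y) {
  name <- match.arg(name, c("zero_rule", "one_rule"))
  fit_classifier(classifier_spec(name), X, y)
}

#' Rank-based AUC (Mann-Whitney, half credit for ties)
#'
#' @param scores numeric scores, larger = more case-like
#' @param y binary 0/1 labels with both classes present
#' @return AUC in \[0, 1\]
#' @export
auc_score <- function(scores, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: single-class labels", call. = FALSE)
  r <- rank(scores)   # midranks give half credit for ties
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

stratified_fold_ids <- function(y, k) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Repeated stratified k-fold cross-validation
#'
#' @param X feature matrix
#' @param y binary 0/1 labels; each class must have at least `k` members
#' @param clf a [classifier_spec()]
#' @param config a [cv_config()]
#' @return list of class `cv_eval` with one [eval_result] per metric
#'   (`accuracy`, `auc`) over the `repeats * k` fold estimates
#' @export
repeated_stratified_cv <- function(X, y, clf, config = cv_config()) {
  X <- as.matrix(X); y <- as.integer(y)
  if (min(table(y)) < config$k)
    stop("smallest class (", min(table(y)), ") has fewer members than k = ",
         config$k, call. = FALSE)
  acc <- auc <- numeric(0)
  with_seed(config$seed, {
    for (r in seq_len(config$repeats)) {
      folds <- stratified_fold_ids(y, config$k)
      for (f in seq_len(config$k)) {
        te <- folds == f
        model <- fit_classifier(clf, X[!te, , drop = FALSE], y[!te])
        pred <- predict(model, X[te, , drop = FALSE], type = "class")
        prob <- predict(model, X[te, , drop = FALSE], type = "prob")
        acc <- c(acc, mean(pred == y[te]))
        auc <- c(auc, if (length(unique(y[te])) == 2) auc_score(prob, y[te]) else NA_real_)
      }
    }
  })
  structure(list(accuracy = eval_result("accuracy", acc),
                 auc = eval_result("auc", auc),
                 config = config, classifier = clf$name), class = "cv_eval")
}

#' @export
print.cv_eval <- function(x, ...) {
  cat(sprintf("%d x %d stratified CV, %s\n", x$config$repeats, x$config$k,
              x$classifier))
  print(x$accuracy); print(x$auc)
  invisible(x)
}

#' Stratified-bootstrap external validation of a fitted model
#'
#' Predictions on the external set are computed once from the already
#' fitted model; every bootstrap replicate then resamples sample indices
#' with replacement within class, so replicate class counts equal the
#' originals exactly, and recomputes accuracy and AUC.
#'
#' @param model a fitted `gf_model` (trained on the discovery cohort)
#' @param X_ext,y_ext external feature matrix and binary 0/1 labels (both
#'   classes required)
#' @param config a [bootstrap_config()]
#' @return list of class `bootstrap_eval` with one [eval_result] per metric
#'   and the point estimates on the unresampled external set
#' @export
stratified_bootstrap_external <- function(model, X_ext, y_ext,
                                          config = bootstrap_config()) {
  stopifnot(inherits(model, "gf_model"))
  X_ext <- as.matrix(X_ext); y_ext <- as.integer(y_ext)
  idx1 <- which(y_ext == 1L); idx0 <- which(y_ext == 0L)
  if (!length(idx1) || !length(idx0))
    stop("external set must contain both classes", call. = FALSE)
  pred <- predict(model, X_ext, type = "class")
  prob <- predict(model, X_ext, type = "prob")
  correct <- pred == y_ext
  acc <- auc <- numeric(config$B)
  with_seed(config$seed, {
    for (b in seq_len(config$B)) {
      s1 <- sample(idx1, length(idx1), replace = TRUE)
      s0 <- sample(idx0, length(idx0), replace = TRUE)
      s <- c(s1, s0)
      acc[b] <- mean(correct[s])
      auc[b] <- auc_score(prob[s], y_ext[s])
    }
  })
  structure(list(accuracy = eval_result("accuracy", acc, config$ci_level),
                 auc = eval_result("auc", auc, config$ci_level),
                 point_accuracy = mean(correct),
                 point_auc = auc_score(prob, y_ext),
                 config = config), class = "bootstrap_eval")
}

#' @export
print.bootstrap_eval <- function(x, ...) {
  cat(sprintf("stratified bootstrap (B = %d)\n", x$config$B))
  print(x$accuracy); print(x$auc)
  invisible(x)
}
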