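#' Best-first wrapper search configuration
#'
#' @param stale_limit consecutive non-improving node expansions tolerated
#'   before the forward search stops (>= 1; `Inf` explores the whole
#'   reachable lattice, equivalent to exhaustive search)
#' @param max_subset_size optional cap on subset size (`Inf` = none)
#' @param metric scored metric; only `"accuracy"` is supported (AUC is
#'   recorded downstream but never optimised)
#' @param screen_top_k optional univariate pre-screen: keep only the
#'   `top_k` features most correlated with the labels before searching.
#'   Inside [embedded_selection_cv()] the screen is recomputed per training
#'   fold, keeping the whole two-stage funnel leakage-free.
#' @param seed integer seed for classifier internals
#' @return a `search_config`
#' @export
search_config <- function(stale_limit = 5, max_subset_size = Inf,
                          metric = "accuracy", screen_top_k = NULL, seed = 1) {
  if (stale_limit < 1) stop("stale_limit must be >= 1", call. = FALSE)
  metric <- match.arg(metric, "accuracy")
  structure(list(direction = "forward", stale_limit = stale_limit,
                 max_subset_size = max_subset_size, metric = metric,
                 screen_top_k = screen_top_k, seed = as.integer(seed)),
            class = "search_config")
}

#' Leave-one-out cross-validated accuracy
#'
#' Runs n train/predict rounds, each holding out one sample; accuracy is
#' the fraction of held-out samples predicted correctly.  For `knn` the
#' equivalent leave-one-out routine of the FNN backend is used (identical
#' protocol, compiled).  A zero-column `X` scores the majority-class rule.
#'
#' @param X numeric feature matrix (samples x features)
#' @param y binary 0/1 labels, both classes present
#' @param clf a [classifier_spec()]
#' @return accuracy in \[0, 1\]
#' @export
loocv_accuracy <- function(X, y, clf) {
  X <- as.matrix(X)
  y <- as.integer(y)
  n <- length(y)
  if (n < 2) stop("need n >= 2 for LOOCV", call. = FALSE)
  if (length(unique(y)) < 2) stop("y must contain both classes", call. = FALSE)
  if (clf$name == "knn" && ncol(X) > 0) {
    k <- min(if (is.null(clf$hyper$k)) 1 else clf$hyper$k, n - 1)
    if (k == 1) {
      # vectorised 1-NN LOOCV: nearest other sample by Euclidean distance,
      # distance ties broken by lowest sample index (deterministic)
      D <- as.matrix(stats::dist(X))
      diag(D) <- Inf
      nn <- max.col(-D, ties.method = "first")
      return(mean(y[nn] == y))
    }
    pred <- FNN::knn.cv(X, factor(y, levels = c(0, 1)), k = k)
    return(mean(as.integer(as.character(pred)) == y))
  }
  correct <- 0L
  for (i in seq_len(n)) {
    model <- fit_classifier(clf, X[-i, , drop = FALSE], y[-i])
    pred <- predict(model, X[i, , drop = FALSE], type = "class")
    correct <- correct + (pred == y[i])
  }
  correct / n
}

#' Univariate candidate screen
#'
#' Ranks features by absolute Pearson correlation with the labels and
#' keeps the top `k` (a fast stand-in for per-feature association ranking
#' in funnel protocols where the screen must be re-run per fold).
#'
#' @param X numeric feature matrix
#' @param y binary 0/1 labels
#' @param top_k number of features to keep
#' @return integer vector of column indices, in original column order
#' @export
screen_candidates <- function(X, y, top_k) {
  X <- as.matrix(X)
  sds <- apply(X, 2, stats::sd)
  r <- rep(0, ncol(X))
  ok <- !is.na(sds) & sds > 0
  r[ok] <- abs(stats::cor(X[, ok, drop = FALSE], y))
  sort(order(-r)[seq_len(min(top_k, ncol(X)))])
}

subset_key <- function(idx) paste0("s:", paste(idx, collapse = ","))

#' Best-first forward search over SNP subsets
#'
#' Classic best-first search on the feature-subset lattice starting from
#' the empty set: an open list ordered by LOOCV accuracy is maintained; the
#' best open node is expanded by all single-feature additions; the search
#' stops after `stale_limit` consecutive expansions that fail to improve
#' the global best (or when the lattice is exhausted).  Ties are broken
#' toward smaller subsets, then lexicographic feature order, so results
#' are deterministic.
#'
#' @inheritParams loocv_accuracy
#' @param config a [search_config()]
#' @return list of class `subset_score`: `features` (column indices, sorted),
#'   `feature_names`, `score`, `n_evaluations`, `trace` (one row per
#'   expansion: subset, node score, best-so-far score)
#' @export
best_first_search <- function(X, y, clf, config = search_config()) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (ncol(X) < 1) stop("need at least one candidate feature", call. = FALSE)
  scores <- new.env(parent = emptyenv())
  n_eval <- 0L
  eval_subset <- function(idx) {
    key <- subset_key(idx)
    if (!is.null(scores[[key]])) return(scores[[key]])
    s <- loocv_accuracy(X[, idx, drop = FALSE], y, clf)
    scores[[key]] <- s
    n_eval <<- n_eval + 1L
    s
  }
  root <- integer(0)
  best_idx <- root
  best_score <- eval_subset(root)
  open_sets <- list(root)
  open_scores <- best_score
  stale <- 0L
  trace <- list()
  while (length(open_sets) > 0 && stale < config$stale_limit) {
    # pop: highest score, ties -> smaller subset, then lexicographic order
    sizes <- lengths(open_sets)
    keys <- vapply(open_sets, subset_key, "")
    ord <- order(-open_scores, sizes, keys)
    pick <- ord[1]
    node <- open_sets[[pick]]
    node_score <- open_scores[pick]
    open_sets <- open_sets[-pick]
    open_scores <- open_scores[-pick]
    improved <- FALSE
    if (length(node) < config$max_subset_size) {
      for (j in setdiff(seq_len(ncol(X)), node)) {
        child <- sort(c(node, j))
        key <- subset_key(child)
        if (!is.null(scores[[key]])) next
        s <- eval_subset(child)
        open_sets[[length(open_sets) + 1]] <- child
        open_scores <- c(open_scores, s)
        if (s > best_score + 1e-9) {
          best_score <- s
          best_idx <- child
          improved <- TRUE
        }
      }
    }
    stale <- if (improved) 0L else stale + 1L
    trace[[length(trace) + 1]] <- data.frame(
      subset = subset_key(node), node_score = node_score,
      best_score = best_score, stringsAsFactors = FALSE)
  }
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(subset = character(0), node_score = numeric(0),
               best_score = numeric(0))
  nm <- colnames(X)
  structure(list(features = best_idx,
                 feature_names = if (!is.null(nm)) nm[best_idx] else as.character(best_idx),
                 score = best_score, n_evaluations = n_eval, trace = trace),
            class = "subset_score")
}

#' @export
print.subset_score <- function(x, ...) {
  cat("subset_score:", length(x$features), "features, LOOCV accuracy",
      sprintf("%.4f", x$score), "(", x$n_evaluations, "evaluations )\n")
  if (length(x$features))
    cat("  features:", paste(x$feature_names, collapse = ", "), "\n")
  invisible(x)
}

#' Fix-once discovery-protocol subset selection
#'
#' Runs one best-first search on the full discovery data (optionally after
#' the univariate screen) and freezes the selected marker set, mirroring
#' the protocol where selection happens once and the resulting markers are
#' reused by every later evaluation.  The returned score is the
#' (optimistic) LOOCV accuracy of the selected subset on the same data.
#'
#' @inheritParams best_first_search
#' @return a `subset_score` whose `features` index columns of `X`
#' @export
fixed_subset_workflow <- function(X, y, clf, config = search_config()) {
  X <- as.matrix(X)
  cand <- if (!is.null(config$screen_top_k))
    screen_candidates(X, y, config$screen_top_k) else seq_len(ncol(X))
  res <- best_first_search(X[, cand, drop = FALSE], y, clf, config)
  res$features <- cand[res$features]
  nm <- colnames(X)
  res$feature_names <- if (!is.null(nm)) nm[res$features] else as.character(res$features)
  res
}

#' Leakage-safe embedded selection under leave-one-out
#'
#' For every held-out sample the entire selection funnel (optional
#' univariate screen, then best-first search) is re-run on the remaining
#' n - 1 samples only; the held-out prediction uses that fold's subset.
#' The honest accuracy aggregates the held-out predictions and is immune
#' to selection leakage, in contrast to [fixed_subset_workflow()].
#'
#' @inheritParams best_first_search
#' @return list of class `embedded_cv`: `honest_accuracy`, `per_fold`
#'   (list with `features` and `score` per fold), `fold_correct` (logical)
#' @export
embedded_selection_cv <- function(X, y, clf, config = search_config()) {
  X <- as.matrix(X)
  y <- as.integer(y)
  n <- length(y)
  if (n < 2) stop("need n >= 2", call. = FALSE)
  if (length(unique(y)) < 2) stop("y must contain both classes", call. = FALSE)
  per_fold <- vector("list", n)
  correct <- logical(n)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]; yi <- y[-i]
    if (length(unique(yi)) < 2) {       # degenerate fold: majority rule
      pred <- as.integer(mean(yi) >= 0.5)
      per_fold[[i]] <- list(features = integer(0), score = NA_real_)
      correct[i] <- pred == y[i]
      next
    }
    sel <- fixed_subset_workflow(Xi, yi, clf, config)
    model <- fit_classifier(clf, Xi[, sel$features, drop = FALSE], yi)
    pred <- predict(model, X[i, sel$features, drop = FALSE], type = "class")
    per_fold[[i]] <- list(features = sel$features, score = sel$score)
    correct[i] <- pred == y[i]
  }
  structure(list(honest_accuracy = mean(correct), per_fold = per_fold,
                 fold_correct = correct), class = "embedded_cv")
}

#' @export
print.embedded_cv <- function(x, ...) {
  cat(sprintf("embedded per-fold selection: honest accuracy %.4f over %d folds\n",
              x$honest_accuracy, length(x$per_fold)))
  invisible(x)
}

#' Write a frozen marker set as TSV
#'
#' @param subset a `subset_score`
#' @param trait trait label for the file
#' @param path output TSV (`trait`, `snp_id`, `rank`)
#' @return `path` invisibly
#' @export
write_marker_set <- function(subset, trait, path) {
  df <- data.frame(trait = rep(trait, length(subset$features)),
                   snp_id = subset$feature_names,
                   rank = seq_along(subset$features), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
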