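#' Classifier specification
#'
#' The registry mirrors the fourteen learners of a standard machine-learning
#' workbench.  `zero_rule` and `one_rule` are fully specified baselines;
#' `knn` binds to the FNN nearest-neighbour backend; the remaining entries
#' are native implementations or documented nearest-equivalent substitutes
#' (see the package vignette): Gaussian naive Bayes, linear soft-margin SVMs
#' trained by batch (`svm_lib`) or stochastic (`svm_sgd`) subgradient
#' descent, maximum-likelihood logistic regression (`smo_logistic`,
#' `logistic_model_tree`), kernel-weighted voting (`lwl`), CART-style
#' decision trees (`c45_tree`, and shallow variants for `ripper`/`part`),
#' a per-split feature-sampled `random_tree`, and a bagged `random_forest`.
#'
#' @param name registry name, one of `naive_bayes`, `svm_lib`, `svm_sgd`,
#'   `smo_logistic`, `knn`, `lwl`, `ripper`, `one_rule`, `part`,
#'   `zero_rule`, `c45_tree`, `logistic_model_tree`, `random_tree`,
#'   `random_forest`
#' @param ... hyperparameters; unknown names are rejected.  Recognised:
#'   `k` (knn), `ntree`/`mtry` (random_forest), `mtry` (random_tree),
#'   `max_depth`/`min_n` (tree learners), `lambda`/`epochs` (SVMs),
#'   `bandwidth` (lwl)
#' @param seed integer seed for classifier-internal randomness
#' @return a `classifier_spec`
#' @export
classifier_spec <- function(name, ..., seed = 1) {
  allowed <- list(
    naive_bayes = character(0),
    svm_lib = c("lambda", "epochs"),
    svm_sgd = c("lambda", "epochs"),
    smo_logistic = character(0),
    knn = "k",
    lwl = c("bandwidth", "k"),
    ripper = c("max_depth", "min_n"),
    one_rule = character(0),
    part = c("max_depth", "min_n"),
    zero_rule = character(0),
    c45_tree = c("max_depth", "min_n"),
    logistic_model_tree = character(0),
    random_tree = c("mtry", "max_depth", "min_n"),
    random_forest = c("ntree", "mtry", "max_depth", "min_n")
  )
  if (!name %in% names(allowed))
    stop("unknown classifier '", name, "'; registry: ",
         paste(names(allowed), collapse = ", "), call. = FALSE)
  hp <- list(...)
  bad <- setdiff(names(hp), allowed[[name]])
  if (length(bad))
    stop("unknown hyperparameter(s) for ", name, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(name = name, hyper = hp, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat("classifier_spec:", x$name)
  if (length(x$hyper))
    cat(" (", paste(names(x$hyper), unlist(x$hyper), sep = "=", collapse = ", "), ")")
  cat("\n")
  invisible(x)
}

# run expr with a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

hp_get <- function(spec, name, default) {
  v <- spec$hyper[[name]]
  if (is.null(v)) default else v
}

#' Fit a registry classifier
#'
#' @param spec a [classifier_spec()]
#' @param X numeric feature matrix (samples x features); a zero-column
#'   matrix is legal and falls back to the majority-class rule
#' @param y binary labels, 0/1 (or coercible)
#' @return a fitted model of class `gf_model`
#' @export
fit_classifier <- function(spec, X, y) {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- as.matrix(X)
  y <- as.integer(y)
  if (nrow(X) == 0 || length(y) == 0) stop("empty training set", call. = FALSE)
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  majority <- if (n1 > n0) 1L else 0L     # tie -> control class 0
  base <- list(spec = spec, majority = majority,
               prior1 = n1 / length(y), p = ncol(X))
  name <- spec$name
  if (ncol(X) == 0 || name == "zero_rule") {
    fitted <- c(base, list(kind = "zero_rule"))
  } else if (name == "one_rule") {
    if (n1 == 0 || n0 == 0) stop("one_rule needs both classes", call. = FALSE)
    best_err <- Inf; best_j <- 1L; best_map <- NULL
    for (j in seq_len(ncol(X))) {
      v <- X[, j]
      lev <- sort(unique(v))
      map <- vapply(lev, function(l) {
        yy <- y[v == l]
        if (sum(yy == 1L) > sum(yy == 0L)) 1L else 0L  # tie -> class 0
      }, 0L)
      pred <- map[match(v, lev)]
      err <- sum(pred != y)
      if (err < best_err) { best_err <- err; best_j <- j; best_map <- list(lev = lev, map = map) }
    }
    fitted <- c(base, list(kind = "one_rule", feature = best_j,
                           lev = best_map$lev, map = best_map$map,
                           train_error = best_err / length(y)))
  } else if (name == "naive_bayes") {
    stats_by <- function(cls) {
      Xi <- X[y == cls, , drop = FALSE]
      mu <- colMeans(Xi)
      sd <- apply(Xi, 2, stats::sd)
      sd[is.na(sd) | sd < 1e-6] <- 1e-6
      list(mu = mu, sd = sd, logprior = log(max(nrow(Xi), 1) / nrow(X)))
    }
    fitted <- c(base, list(kind = "naive_bayes", c0 = stats_by(0L), c1 = stats_by(1L)))
  } else if (name == "knn") {
    fitted <- c(base, list(kind = "knn", X = X, y = y, k = hp_get(spec, "k", 1)))
  } else if (name == "lwl") {
    d <- stats::dist(X)
    bw <- hp_get(spec, "bandwidth", stats::median(d[d > 0]))
    if (!is.finite(bw) || bw <= 0) bw <- 1
    fitted <- c(base, list(kind = "lwl", X = X, y = y, bw = bw))
  } else if (name %in% c("smo_logistic", "logistic_model_tree")) {
    Xd <- cbind(1, X)
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(Xd, y, family = stats::binomial())),
      error = function(e) NULL)
    beta <- if (is.null(fit)) rep(0, ncol(Xd)) else fit$coefficients
    beta[is.na(beta)] <- 0
    beta <- pmin(pmax(beta, -30), 30)   # cap runaway separation fits
    fitted <- c(base, list(kind = "logistic", beta = beta))
  } else if (name %in% c("svm_lib", "svm_sgd")) {
    mu <- colMeans(X); sdv <- apply(X, 2, stats::sd)
    sdv[sdv == 0 | is.na(sdv)] <- 1
    Z <- sweep(sweep(X, 2, mu, `-`), 2, sdv, `/`)
    yy <- ifelse(y == 1L, 1, -1)
    lambda <- hp_get(spec, "lambda", 0.01)
    epochs <- hp_get(spec, "epochs", if (name == "svm_lib") 200 else 50)
    w <- rep(0, ncol(Z)); b <- 0
    n <- nrow(Z)
    if (name == "svm_lib") {
      for (t in seq_len(epochs)) {           # full-batch subgradient descent
        eta <- 1 / (lambda * t)
        marg <- yy * (Z %*% w + b)
        viol <- marg < 1
        gw <- lambda * w - colSums(Z[viol, , drop = FALSE] * yy[viol]) / n
        gb <- -sum(yy[viol]) / n
        w <- w - eta * gw; b <- b - eta * gb
      }
    } else {
      with_seed(spec$seed, {                  # Pegasos-style SGD
        t <- 0
        for (ep in seq_len(epochs)) {
          for (i in sample.int(n)) {
            t <- t + 1
            eta <- 1 / (lambda * t)
            if (yy[i] * (sum(Z[i, ] * w) + b) < 1) {
              w <- (1 - eta * lambda) * w + eta * yy[i] * Z[i, ]
              b <- b + eta * yy[i]
            } else {
              w <- (1 - eta * lambda) * w
            }
          }
        }
      })
    }
    fitted <- c(base, list(kind = "linear_svm", w = w, b = b, mu = mu, sd = sdv))
  } else if (name %in% c("c45_tree", "part", "ripper")) {
    depth <- hp_get(spec, "max_depth", if (name == "c45_tree") 6 else 3)
    min_n <- hp_get(spec, "min_n", 4)
    tree <- cart_build(X, y, depth = depth, min_n = min_n, mtry = ncol(X))
    fitted <- c(base, list(kind = "cart", tree = tree))
  } else if (name == "random_tree") {
    mtry <- hp_get(spec, "mtry", max(1, ceiling(sqrt(ncol(X)))))
    tree <- with_seed(spec$seed,
                      cart_build(X, y, depth = hp_get(spec, "max_depth", 10),
                                 min_n = hp_get(spec, "min_n", 2), mtry = mtry))
    fitted <- c(base, list(kind = "cart", tree = tree))
  } else if (name == "random_forest") {
    ntree <- hp_get(spec, "ntree", 100)
    mtry <- hp_get(spec, "mtry", max(1, ceiling(sqrt(ncol(X)))))
    depth <- hp_get(spec, "max_depth", 10)
    min_n <- hp_get(spec, "min_n", 2)
    n <- nrow(X)
    trees <- with_seed(spec$seed, lapply(seq_len(ntree), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      cart_build(X[idx, , drop = FALSE], y[idx], depth = depth,
                 min_n = min_n, mtry = mtry)
    }))
    fitted <- c(base, list(kind = "forest", trees = trees))
  } else {
    stop("unhandled classifier: ", name, call. = FALSE)
  }
  structure(fitted, class = "gf_model")
}

#' Predict from a fitted registry classifier
#'
#' @param object a `gf_model`
#' @param newdata numeric feature matrix with the training column count
#' @param type `"class"` (0/1 labels) or `"prob"` (score for class 1; for
#'   margin-based learners a monotone transform of the decision value, so
#'   ranks -- and hence AUC -- are meaningful)
#' @param ... unused
#' @export
predict.gf_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (object$p > 0 && ncol(X) != object$p && object$kind != "zero_rule")
    stop("newdata has ", ncol(X), " columns, model expects ", object$p, call. = FALSE)
  n <- nrow(X)
  prob <- switch(object$kind,
    zero_rule = rep(object$prior1, n),
    one_rule = {
      v <- X[, object$feature]
      idx <- match(v, object$lev)
      pred <- object$map[idx]
      pred[is.na(pred)] <- object$majority   # unseen value -> majority
      # class probabilities are degenerate for a rule learner
      ifelse(pred == 1L, 1, 0)
    },
    naive_bayes = {
      loglik <- function(cls) {
        ll <- rep(cls$logprior, n)
        for (j in seq_len(ncol(X)))
          ll <- ll + stats::dnorm(X[, j], cls$mu[j], cls$sd[j], log = TRUE)
        ll
      }
      l0 <- loglik(object$c0); l1 <- loglik(object$c1)
      1 / (1 + exp(l0 - l1))
    },
    knn = {
      k <- min(object$k, nrow(object$X))
      pr <- FNN::knn(object$X, X, factor(object$y, levels = c(0, 1)),
                     k = k, prob = TRUE)
      win <- as.integer(as.character(pr))
      frac <- attr(pr, "prob")
      ifelse(win == 1L, frac, 1 - frac)
    },
    lwl = {
      d2 <- outer(rowSums(X^2), rowSums(object$X^2), `+`) -
        2 * tcrossprod(X, object$X)
      w <- exp(-pmax(d2, 0) / (2 * object$bw^2))
      rs <- rowSums(w)
      ifelse(rs > 0, as.vector(w %*% object$y) / rs, object$prior1)
    },
    logistic = stats::plogis(as.vector(cbind(1, X) %*% object$beta)),
    linear_svm = {
      Z <- sweep(sweep(X, 2, object$mu, `-`), 2, object$sd, `/`)
      stats::plogis(as.vector(Z %*% object$w) + object$b)
    },
    cart = cart_predict(object$tree, X),
    forest = {
      acc <- rep(0, n)
      for (tr in object$trees) acc <- acc + (cart_predict(tr, X) >= 0.5)
      acc / length(object$trees)
    },
    stop("unknown model kind", call. = FALSE)
  )
  if (type == "prob") return(as.numeric(prob))
  if (object$kind == "zero_rule") return(rep(object$majority, n))
  as.integer(prob >= 0.5)
}

# ---- minimal CART (gini, binary classification, numeric features) ----

cart_build <- function(X, y, depth, min_n, mtry) {
  n <- length(y)
  n1 <- sum(y)
  node_prob <- if (n > 0) n1 / n else 0.5
  leaf <- list(leaf = TRUE, prob = node_prob)
  if (depth <= 0 || n < min_n || n1 == 0 || n1 == n) return(leaf)
  feats <- if (mtry >= ncol(X)) seq_len(ncol(X)) else sample.int(ncol(X), mtry)
  best <- NULL; best_gini <- Inf
  parent_gini <- 2 * node_prob * (1 - node_prob)
  for (j in feats) {
    v <- X[, j]
    ord <- order(v)
    vs <- v[ord]; ys <- y[ord]
    cum1 <- cumsum(ys); cumn <- seq_len(n)
    cut_ok <- which(vs[-n] < vs[-1])       # split between distinct values
    if (!length(cut_ok)) next
    nl <- cumn[cut_ok]; n1l <- cum1[cut_ok]
    nr <- n - nl; n1r <- n1 - n1l
    pl <- n1l / nl; pr <- n1r / nr
    g <- (nl * 2 * pl * (1 - pl) + nr * 2 * pr * (1 - pr)) / n
    k <- which.min(g)
    if (g[k] < best_gini - 1e-12) {
      best_gini <- g[k]
      cutpoint <- (vs[cut_ok[k]] + vs[cut_ok[k] + 1]) / 2
      best <- list(j = j, cut = cutpoint)
    }
  }
  if (is.null(best) || best_gini >= parent_gini - 1e-12) return(leaf)
  go_l <- X[, best$j] <= best$cut
  list(leaf = FALSE, j = best$j, cut = best$cut, prob = node_prob,
       left = cart_build(X[go_l, , drop = FALSE], y[go_l], depth - 1, min_n, mtry),
       right = cart_build(X[!go_l, , drop = FALSE], y[!go_l], depth - 1, min_n, mtry))
}

cart_predict <- function(tree, X) {
  n <- nrow(X)
  out <- numeric(n)
  rec <- function(node, idx) {
    if (!length(idx)) return()
    if (node$leaf) { out[idx] <<- node$prob; return() }
    go_l <- X[idx, node$j] <= node$cut
    rec(node$left, idx[go_l])
    rec(node$right, idx[!go_l])
  }
  rec(tree, seq_len(n))
  out
}
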