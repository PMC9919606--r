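# The eight-classifier roster, configured with the reference defaults:
# AdaBoost (50 stumps, real boosting), CART decision tree (gini, unlimited
# depth), kNN (k = 5, Euclidean), LDA, L2-regularized logistic regression
# (C = 1), random forest (100 gini trees, sqrt(p) features, bootstrap),
# and C-SVM with linear and RBF kernels (C = 1, gamma = "scale").
#
# Trees, forests, boosting and the SVM are solved by the package's own
# compiled CART and SMO kernels (no suitable implementations are assumed to
# be installed); LDA uses MASS and the ridge-logistic uses glmnet with
# lambda = 1 / (n * C), the penalty equivalent of the reference
# parameterization.

CLASSIFIER_FAMILIES <- c("adaboost", "decision_tree", "knn", "lda",
                         "logistic", "random_forest", "svm_linear", "svm_rbf")

#' Classifier specification
#'
#' @param family one of `"adaboost"`, `"decision_tree"`, `"knn"`, `"lda"`,
#'   `"logistic"`, `"random_forest"`, `"svm_linear"`, `"svm_rbf"`.
#' @param seed integer seed consumed by stochastic families (forest
#'   bootstraps and feature subsampling); deterministic families ignore it.
#' @param params named list of hyperparameter overrides; anything not given
#'   keeps the roster default.
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(family, seed = 1L, params = list()) {
  family <- match.arg(family, CLASSIFIER_FAMILIES)
  defaults <- switch(family,
    adaboost = list(n_estimators = 50L, learning_rate = 1.0, max_depth = 1L),
    decision_tree = list(max_depth = -1L, min_samples_split = 2L,
                         min_samples_leaf = 1L),
    knn = list(k = 5L),
    lda = list(),
    logistic = list(C = 1.0),
    random_forest = list(n_estimators = 100L, max_depth = -1L,
                         min_samples_split = 2L, min_samples_leaf = 1L),
    svm_linear = list(C = 1.0, tol = 1e-3),
    svm_rbf = list(C = 1.0, tol = 1e-3, gamma = "scale"))
  defaults[names(params)] <- params
  structure(list(family = family, seed = as.integer(seed), params = defaults),
            class = "classifier_spec")
}

#' @rdname classifier_spec
#' @param seed base seed from which each family derives its own stream.
#' @export
default_roster <- function(seed = 1L) {
  lapply(CLASSIFIER_FAMILIES, function(f)
    classifier_spec(f, seed = derive_seed(seed, "model", f)))
}

as_feature_matrix <- function(rows, feats = pain_feature_names()) {
  as.matrix(rows[, feats, drop = FALSE])
}

# ---- family fitters ---------------------------------------------------------

fit_tree <- function(X, y, w = NULL, max_depth = -1L, min_split = 2L,
                     min_leaf = 1L, mtry = 0L) {
  if (is.null(w)) w <- rep(1, nrow(X))
  .cart_fit(X, as.integer(y), w, as.integer(max_depth), as.integer(min_split),
            as.integer(min_leaf), as.integer(mtry))
}

fit_random_forest <- function(X, y, p, n_estimators, max_depth, min_split,
                              min_leaf) {
  n <- nrow(X)
  mtry <- max(1L, floor(sqrt(p)))
  trees <- vector("list", n_estimators)
  imp <- numeric(p)
  for (t in seq_len(n_estimators)) {
    idx <- sample.int(n, n, replace = TRUE)
    trees[[t]] <- fit_tree(X[idx, , drop = FALSE], y[idx],
                           max_depth = max_depth, min_split = min_split,
                           min_leaf = min_leaf, mtry = mtry)
    imp <- imp + trees[[t]]$importance
  }
  list(trees = trees, importance = imp / n_estimators)
}

fit_adaboost <- function(X, y, n_estimators, learning_rate, max_depth) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  stumps <- list()
  eps <- 1e-10
  for (t in seq_len(n_estimators)) {
    st <- fit_tree(X, y, w = w, max_depth = max_depth)
    pr <- .cart_predict(st, X)
    pr <- pmin(pmax(pr, eps), 1 - eps)
    # real boosting (SAMME.R): half log-odds as the stage decision function
    h <- 0.5 * (log(pr[, 2]) - log(pr[, 1]))
    stumps[[t]] <- st
    err <- sum(w * ((pr[, 2] > pr[, 1]) != (y == 1)))
    if (err <= 0) break
    ys <- ifelse(y == 1, 1, -1)
    w <- w * exp(-learning_rate * ys * h)
    w <- w / sum(w)
  }
  imp <- Reduce(`+`, lapply(stumps, `[[`, "importance")) / length(stumps)
  list(stumps = stumps, learning_rate = learning_rate, importance = imp)
}

svm_gamma <- function(gamma, X) {
  if (identical(gamma, "scale")) {
    v <- mean(X^2) - mean(X)^2
    if (v <= 0) v <- 1
    1 / (ncol(X) * v)
  } else as.numeric(gamma)
}

# ---- unified fit / predict --------------------------------------------------

#' Fit one classifier of the roster
#'
#' @param spec a [classifier_spec()].
#' @param rows training rows of a labeled feature table (need a `label`
#'   column and the 21 feature columns), or a data.frame with arbitrary
#'   numeric feature columns plus `label`.
#' @param feats feature column names (defaults to the 21 canonical ones).
#' @return a fitted `pain_model`; use [predict.pain_model()].
#' @export
train_classifier <- function(spec, rows, feats = pain_feature_names()) {
  stopifnot(inherits(spec, "classifier_spec"))
  y <- rows$label
  if (length(unique(y)) < 2)
    stop_input("training set contains a single class")
  X <- as_feature_matrix(rows, feats)
  p <- spec$params
  set.seed(spec$seed)
  fit <- switch(spec$family,
    adaboost = fit_adaboost(X, y, p$n_estimators, p$learning_rate, p$max_depth),
    decision_tree = fit_tree(X, y, max_depth = p$max_depth,
                             min_split = p$min_samples_split,
                             min_leaf = p$min_samples_leaf),
    knn = list(X = X, y = y, k = min(p$k, nrow(X))),
    lda = MASS::lda(X, grouping = factor(y, levels = c(0, 1))),
    logistic = glmnet::glmnet(X, factor(y, levels = c(0, 1)),
                              family = "binomial", alpha = 0,
                              lambda = 1 / (nrow(X) * p$C),
                              standardize = FALSE),
    random_forest = fit_random_forest(X, y, ncol(X), p$n_estimators,
                                      p$max_depth, p$min_samples_split,
                                      p$min_samples_leaf),
    svm_linear = .svm_fit(X, ifelse(y == 1, 1, -1), p$C, FALSE, 0, p$tol, -1L),
    svm_rbf = {
      g <- svm_gamma(p$gamma, X)
      c(.svm_fit(X, ifelse(y == 1, 1, -1), p$C, TRUE, g, p$tol, -1L),
        list(gamma = g))
    })
  structure(list(spec = spec, fit = fit, feats = feats),
            class = "pain_model")
}

#' Predict class labels (0/1) from a fitted model
#'
#' @param object a `pain_model`.
#' @param newdata data.frame containing the model's feature columns.
#' @param type `"label"` (default) or `"decision"` for a real-valued score
#'   where the family provides one.
#' @param ... unused.
#' @export
predict.pain_model <- function(object, newdata, type = c("label", "decision"),
                               ...) {
  type <- match.arg(type)
  X <- as_feature_matrix(newdata, object$feats)
  fam <- object$spec$family
  fit <- object$fit
  dec <- switch(fam,
    adaboost = {
      eps <- 1e-10
      acc <- numeric(nrow(X))
      for (st in fit$stumps) {
        pr <- pmin(pmax(.cart_predict(st, X), eps), 1 - eps)
        acc <- acc + 0.5 * (log(pr[, 2]) - log(pr[, 1]))
      }
      acc
    },
    decision_tree = .cart_predict(fit, X)[, 2] - 0.5,
    knn = {
      votes <- knn_votes(fit$X, fit$y, X, fit$k)
      votes - 0.5
    },
    lda = {
      post <- predict(fit, X)$posterior[, "1"]
      post - 0.5
    },
    logistic = as.numeric(predict(fit, X, type = "link")),
    random_forest = {
      acc <- numeric(nrow(X))
      for (tr in fit$trees) acc <- acc + .cart_predict(tr, X)[, 2]
      acc / length(fit$trees) - 0.5
    },
    svm_linear = as.numeric(.svm_decision(fit$sv, fit$coef, fit$b, X, FALSE, 0)),
    svm_rbf = as.numeric(.svm_decision(fit$sv, fit$coef, fit$b, X, TRUE,
                                       fit$gamma)))
  if (type == "decision") return(dec)
  as.integer(dec > 0)
}

# fraction of the k nearest training rows labeled 1, per test row
knn_votes <- function(Xtr, ytr, Xte, k) {
  # squared Euclidean distances via the expansion trick, fully vectorized
  d2 <- outer(rowSums(Xte^2), rowSums(Xtr^2), "+") - 2 * Xte %*% t(Xtr)
  apply(d2, 1, function(d) mean(ytr[order(d)[seq_len(k)]] == 1))
}
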