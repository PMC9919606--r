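# Per-model feature importance, min-max rescaled to [0, 1] so rankings can
# be compared across model families:
#   - linear families (LDA, logistic): absolute coefficient magnitudes;
#   - tree families (decision tree, random forest, AdaBoost): total
#     gini-impurity decrease;
#   - SVM and kNN: permutation importance — mean drop in balanced accuracy
#     on the test rows over seeded shuffles of one feature column at a time.

#' Raw per-feature importance of a fitted model
#'
#' @param model a fitted `pain_model`.
#' @param test_rows labeled rows used by the permutation families (ignored by
#'   coefficient and impurity families).
#' @param n_repeats permutation repeats (permutation families only; must be
#'   >= 1 there).
#' @param seed seed for the permutations.
#' @return named numeric vector over the model's features.
#' @export
raw_importance <- function(model, test_rows = NULL, n_repeats = 10L,
                           seed = 1L) {
  stopifnot(inherits(model, "pain_model"))
  feats <- model$feats
  fam <- model$spec$family
  out <- switch(fam,
    lda = abs(model$fit$scaling[, 1]),
    logistic = abs(as.numeric(coef(model$fit))[-1]),
    decision_tree = model$fit$importance,
    random_forest = model$fit$importance,
    adaboost = model$fit$importance,
    svm_linear = ,
    svm_rbf = ,
    knn = {
      if (is.null(test_rows)) stop_input("permutation importance needs test rows")
      if (n_repeats < 1) stop_input("n_repeats must be >= 1 for permutation importance")
      permutation_importance(model, test_rows, n_repeats, seed)
    },
    stop_input("unknown model family %s", fam))
  stats::setNames(as.numeric(out), feats)
}

#' Permutation importance scored by balanced accuracy
#'
#' @param model fitted `pain_model`.
#' @param rows labeled rows to score on.
#' @param n_repeats shuffles per feature.
#' @param seed RNG seed.
#' @return named vector of mean balanced-accuracy drops.
#' @export
permutation_importance <- function(model, rows, n_repeats = 10L, seed = 1L) {
  feats <- model$feats
  base <- compute_metrics(rows$label,
                          predict(model, rows))$balanced_accuracy
  set.seed(as.integer(seed))
  drops <- sapply(feats, function(f) {
    mean(replicate(n_repeats, {
      shuffled <- rows
      shuffled[[f]] <- sample(shuffled[[f]])
      base - compute_metrics(rows$label,
                             predict(model, shuffled))$balanced_accuracy
    }))
  })
  stats::setNames(drops, feats)
}

#' Min-max rescaling of raw importance scores to [0, 1]
#'
#' `scaled = (raw - min) / (max - min)`. If all raw scores are equal the
#' range is zero; the scores are then returned as all-zero with attribute
#' `degenerate = TRUE` rather than failing, to keep batch runs alive.
#'
#' @param raw numeric vector of at least 2 scores.
#' @return rescaled vector in [0, 1].
#' @export
minmax_scale <- function(raw) {
  if (length(raw) < 2) stop_input("min-max scaling needs at least 2 scores")
  rng <- range(raw)
  if (diff(rng) == 0)
    return(structure(rep(0, length(raw)), names = names(raw),
                     degenerate = TRUE))
  (raw - rng[1]) / (rng[2] - rng[1])
}

#' Importance table for a roster of fitted models
#'
#' @param models named list of fitted `pain_model`s (names = families).
#' @param test_rows labeled rows for the permutation families.
#' @param n_repeats,seed permutation parameters.
#' @return long data.frame `model`, `feature`, `raw`, `scaled`.
#' @export
importance_table <- function(models, test_rows = NULL, n_repeats = 10L,
                             seed = 1L) {
  out <- lapply(names(models), function(nm) {
    raw <- raw_importance(models[[nm]], test_rows, n_repeats,
                          seed = derive_seed(seed, "perm", nm))
    data.frame(model = nm, feature = names(raw), raw = as.numeric(raw),
               scaled = as.numeric(minmax_scale(raw)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-model rankings and the cross-model consensus
#'
#' The consensus score of a feature is its mean scaled score across models;
#' ties are broken by feature-name order (alphabetical), which is stable and
#' documented.
#'
#' @param imp long importance table from [importance_table()].
#' @param k how many top features to report.
#' @return list with `per_model` (data.frame model/rank/feature/scaled),
#'   `consensus` (data.frame feature/mean_scaled, ordered), `top_k`.
#' @export
rank_report <- function(imp, k = 5L) {
  stopifnot(all(c("model", "feature", "scaled") %in% names(imp)))
  counts <- table(imp$model)
  if (length(unique(counts)) != 1 ||
      !all(tapply(imp$feature, imp$model, function(f)
        setequal(f, imp$feature[imp$model == imp$model[1]]))))
    stop_input("models carry mismatched feature sets")
  per_model <- do.call(rbind, lapply(split(imp, imp$model), function(d) {
    d <- d[order(-d$scaled, d$feature), ]
    d$rank <- seq_len(nrow(d))
    d[, c("model", "rank", "feature", "scaled")]
  }))
  rownames(per_model) <- NULL
  cons <- stats::aggregate(scaled ~ feature, imp, mean)
  names(cons)[2] <- "mean_scaled"
  cons <- cons[order(-cons$mean_scaled, cons$feature), ]
  rownames(cons) <- NULL
  list(per_model = per_model, consensus = cons,
       top_k = head(cons$feature, k))
}

#' Fit the roster once and produce its importance report
#'
#' Models are fitted on the training rows of the plan's first evaluation and
#' permutation families are scored on that evaluation's test rows (for the
#' session-independent approach this is the single train/test split).
#'
#' @param table labeled feature table.
#' @param approach evaluation approach.
#' @param roster list of [classifier_spec()]; default full roster.
#' @param seed integer seed.
#' @param n_repeats permutation repeats.
#' @return list with `importance` (long table) and `ranking` ([rank_report()]).
#' @export
importance_for_approach <- function(table, approach, roster = NULL,
                                    seed = 1L, n_repeats = 10L) {
  if (is.null(roster)) roster <- default_roster(seed)
  plan <- build_split(approach, table, seed = derive_seed(seed, "split", approach))
  ev <- plan$evaluations[[1]]
  models <- stats::setNames(lapply(roster, function(spec)
    train_classifier(classifier_spec(spec$family,
                                     seed = derive_seed(seed, spec$family, 1L),
                                     params = spec$params),
                     table[ev$train, , drop = FALSE])),
    vapply(roster, `[[`, character(1), "family"))
  imp <- importance_table(models, table[ev$test, , drop = FALSE],
                          n_repeats = n_repeats, seed = seed)
  list(importance = imp, ranking = rank_report(imp))
}
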