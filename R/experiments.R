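# The three train/test designs and the six evaluation metrics.
#
# dependent: 5 repetitions of stratified 2-fold CV over all rows of both
#   sessions (10 evaluations; rows of one participant-session may appear on
#   either side, never the same row on both).
# session_independent: train on every session-1 (fear-context) row, test on
#   every session-2 (neutral-context) row.
# participant_independent: leave-one-participant-out; for each participant,
#   train on session-1 rows of all the others and test on that participant's
#   session-2 rows.

APPROACHES <- c("dependent", "session_independent", "participant_independent")

#' Build a split plan for one evaluation approach
#'
#' @param approach one of `"dependent"`, `"session_independent"`,
#'   `"participant_independent"`.
#' @param table labeled feature table (needs `participant`, `session`,
#'   `label`).
#' @param seed integer seed (used by the dependent approach's shuffles).
#' @param n_repeats,n_folds dependent-approach geometry (5 x 2 by default).
#' @return object of class `split_plan`: list with `approach`, `seed` and
#'   `evaluations`, each evaluation a list of disjoint integer row-index
#'   vectors `train` and `test`.
#' @export
build_split <- function(approach, table, seed = 1L, n_repeats = 5L,
                        n_folds = 2L) {
  approach <- match.arg(approach, APPROACHES)
  stopifnot(all(c("participant", "session", "label") %in% names(table)))
  n <- nrow(table)
  evals <- list()
  if (approach == "dependent") {
    for (r in seq_len(n_repeats)) {
      set.seed(derive_seed(seed, "rep", r))
      fold <- integer(n)
      for (cl in unique(table$label)) { # stratified fold assignment
        idx <- sample(which(table$label == cl))
        fold[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
      for (f in seq_len(n_folds))
        evals[[length(evals) + 1]] <- list(train = which(fold != f),
                                           test = which(fold == f))
    }
  } else if (approach == "session_independent") {
    if (length(unique(table$session)) < 2)
      stop_input("session-independent design needs two sessions")
    evals[[1]] <- list(train = which(table$session == 1),
                       test = which(table$session == 2))
  } else {
    if (length(unique(table$session)) < 2)
      stop_input("participant-independent design needs two sessions")
    for (p in sort(unique(table$participant)))
      evals[[length(evals) + 1]] <- list(
        train = which(table$session == 1 & table$participant != p),
        test = which(table$session == 2 & table$participant == p))
    evals <- Filter(function(e) length(e$test) > 0, evals)
  }
  for (e in evals)
    if (length(intersect(e$train, e$test)) > 0)
      stop("internal error: train/test overlap")
  structure(list(approach = approach, seed = seed, evaluations = evals),
            class = "split_plan")
}

#' Six-metric evaluation of binary predictions
#'
#' CPT (1) is the positive class. Ratios with a zero denominator are
#' returned as 0 and recorded in the `flags` field.
#'
#' @param truth,predicted equal-length 0/1 label vectors.
#' @return object of class `metrics_report`: list with `counts` (TP, FP, FN,
#'   TN), the six metrics (`accuracy`, `balanced_accuracy`, `f1`, `mcc`,
#'   `precision`, `recall`), and `flags`.
#' @export
compute_metrics <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop_input("label vectors differ in length")
  if (!all(truth %in% c(0, 1)) || !all(predicted %in% c(0, 1)))
    stop_input("labels must be binary 0/1")
  tp <- sum(truth == 1 & predicted == 1)
  fp <- sum(truth == 0 & predicted == 1)
  fn <- sum(truth == 1 & predicted == 0)
  tn <- sum(truth == 0 & predicted == 0)
  flags <- character(0)
  safe_div <- function(num, den, name) {
    if (den == 0) {
      flags <<- c(flags, name)
      return(0)
    }
    num / den
  }
  recall <- safe_div(tp, tp + fn, "recall")
  specificity <- safe_div(tn, tn + fp, "specificity")
  precision <- safe_div(tp, tp + fp, "precision")
  f1 <- safe_div(2 * precision * recall, precision + recall, "f1")
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) {
    flags <- c(flags, "mcc")
    0
  } else (tp * tn - fp * fn) / mcc_den
  structure(list(
    counts = c(TP = tp, FP = fp, FN = fn, TN = tn),
    accuracy = (tp + tn) / length(truth),
    balanced_accuracy = (recall + specificity) / 2,
    f1 = f1, mcc = mcc, precision = precision, recall = recall,
    flags = flags), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> TP %d FP %d FN %d TN %d | acc %.3f balacc %.3f f1 %.3f mcc %.3f prec %.3f rec %.3f\n",
              x$counts["TP"], x$counts["FP"], x$counts["FN"], x$counts["TN"],
              x$accuracy, x$balanced_accuracy, x$f1, x$mcc, x$precision,
              x$recall))
  invisible(x)
}

metric_names <- function() {
  c("accuracy", "balanced_accuracy", "f1", "mcc", "precision", "recall")
}

#' Run one approach over a classifier roster
#'
#' Fits every model on every evaluation of the plan, predicts the held-out
#' rows, and reports the unweighted mean of each metric across evaluations
#' alongside the per-evaluation detail. Per-model sub-seeds derive
#' deterministically from `seed`, so the whole experiment is reproducible.
#' A failing evaluation (for example a degenerate training set) is recorded
#' and the remaining ones continue.
#'
#' @param table labeled, normalized feature table from [assemble_dataset()].
#' @param approach evaluation approach, see [build_split()].
#' @param roster list of [classifier_spec()]; defaults to the full
#'   eight-family roster.
#' @param seed integer experiment seed.
#' @return object of class `experiment_result` with `summary` (data.frame:
#'   model, approach, metric, value), `detail` (per evaluation), `plan`,
#'   `failures`.
#' @export
run_experiment <- function(table, approach, roster = NULL, seed = 1L) {
  if (is.null(roster)) roster <- default_roster(seed)
  plan <- build_split(approach, table, seed = derive_seed(seed, "split", approach))
  detail <- list()
  failures <- list()
  for (spec in roster) {
    for (ei in seq_along(plan$evaluations)) {
      ev <- plan$evaluations[[ei]]
      res <- tryCatch({
        sp <- classifier_spec(spec$family,
                              seed = derive_seed(seed, spec$family, ei),
                              params = spec$params)
        model <- train_classifier(sp, table[ev$train, , drop = FALSE])
        pred <- predict(model, table[ev$test, , drop = FALSE])
        m <- compute_metrics(table$label[ev$test], pred)
        data.frame(model = spec$family, approach = approach, evaluation = ei,
                   metric = metric_names(),
                   value = unlist(m[metric_names()], use.names = FALSE))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1]] <-
          list(model = spec$family, evaluation = ei,
               message = conditionMessage(res))
      } else {
        detail[[length(detail) + 1]] <- res
      }
    }
  }
  detail <- do.call(rbind, detail)
  summary <- stats::aggregate(value ~ model + approach + metric, detail, mean)
  structure(list(summary = summary, detail = detail, plan = plan,
                 failures = failures, seed = seed),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %s: %d models x %d evaluations (%d failures)\n",
              x$plan$approach, length(unique(x$summary$model)),
              length(x$plan$evaluations), length(x$failures)))
  print(summary_matrix(x))
  invisible(x)
}

#' Summary metrics as a models-by-metrics matrix
#' @param result an `experiment_result`.
#' @export
summary_matrix <- function(result) {
  s <- result$summary
  models <- sort(unique(s$model))
  m <- sapply(models, function(mod)
    sapply(metric_names(), function(met)
      s$value[s$model == mod & s$metric == met]))
  round(t(m), 3)
}
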