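# split plans, metrics, experiment runner

make_label_table <- function(n_participants = 4, n_sessions = 2,
                             n_base = 6, n_cpt = 3, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(participant = seq_len(n_participants),
                      session = seq_len(n_sessions))
  rows <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    k <- n_base + n_cpt
    d <- data.frame(participant = grid$participant[i],
                    session = grid$session[i],
                    epoch = rep(c("baseline", "cpt"), c(n_base, n_cpt)),
                    window_start = seq_len(k),
                    label = rep(c(0L, 1L), c(n_base, n_cpt)))
    for (f in pain_feature_names())
      d[[f]] <- rnorm(k, mean = ifelse(d$label == 1, 1.5, 1), sd = 0.1)
    d
  }))
  rows
}

test_that("dependent plan: 10 stratified disjoint evaluations", {
  tab <- make_label_table()
  plan <- build_split("dependent", tab, seed = 3)
  expect_length(plan$evaluations, 10)
  for (ev in plan$evaluations) {
    expect_length(intersect(ev$train, ev$test), 0)
    expect_setequal(c(ev$train, ev$test), seq_len(nrow(tab)))
    # stratification: fold class counts differ by at most 1
    expect_lte(abs(sum(tab$label[ev$train] == 1) - sum(tab$label[ev$test] == 1)), 1)
  }
  # seeded reproducibility
  plan2 <- build_split("dependent", tab, seed = 3)
  expect_identical(plan, plan2)
})

test_that("session-independent plan partitions by session", {
  tab <- make_label_table()
  plan <- build_split("session_independent", tab, seed = 1)
  expect_length(plan$evaluations, 1)
  ev <- plan$evaluations[[1]]
  expect_true(all(tab$session[ev$train] == 1))
  expect_true(all(tab$session[ev$test] == 2))
  expect_length(intersect(ev$train, ev$test), 0)
  one_session <- tab[tab$session == 1, ]
  expect_error(build_split("session_independent", one_session), "two sessions")
})

test_that("participant-independent plan is leave-one-participant-out", {
  tab <- make_label_table(n_participants = 5)
  plan <- build_split("participant_independent", tab, seed = 1)
  expect_length(plan$evaluations, 5)
  for (ev in plan$evaluations) {
    test_p <- unique(tab$participant[ev$test])
    expect_length(test_p, 1)
    expect_true(all(tab$session[ev$test] == 2))
    expect_true(all(tab$session[ev$train] == 1))
    expect_false(test_p %in% tab$participant[ev$train])
  }
})

test_that("compute_metrics matches the worked confusion matrix to 4 d.p.", {
  truth <- rep(c(1, 1, 0, 0), c(50, 10, 5, 35))
  pred <- rep(c(1, 0, 1, 0), c(50, 10, 5, 35))
  m <- compute_metrics(truth, pred)
  expect_equal(unname(m$counts), c(50, 5, 10, 35))
  expect_equal(round(m$recall, 4), 0.8333)
  expect_equal(round(m$precision, 4), 0.9091)
  expect_equal(round(m$balanced_accuracy, 4), 0.8542)
  expect_equal(round(m$f1, 4), 0.8696)
  expect_equal(round(m$mcc, 4), 0.6975)
  expect_equal(m$accuracy, 0.85)
})

test_that("metric edge cases: perfection, degeneracy, bad input", {
  perf <- compute_metrics(c(0, 1, 1, 0), c(0, 1, 1, 0))
  for (met in c("accuracy", "balanced_accuracy", "f1", "mcc", "precision",
                "recall"))
    expect_equal(perf[[met]], 1, label = met)
  allneg <- compute_metrics(c(0, 1, 1, 0), c(0, 0, 0, 0))
  expect_equal(allneg$recall, 0)
  expect_equal(allneg$precision, 0)
  expect_true("precision" %in% allneg$flags)
  expect_equal(allneg$balanced_accuracy, 0.5)
  expect_error(compute_metrics(c(0, 1), c(1)), "length")
  expect_error(compute_metrics(c(0, 2), c(1, 0)), "binary")
})

test_that("run_experiment aggregates, reproduces, and bounds its mean", {
  tab <- make_label_table(n_participants = 4)
  roster <- list(classifier_spec("lda"), classifier_spec("decision_tree"))
  r1 <- run_experiment(tab, "dependent", roster = roster, seed = 9)
  r2 <- run_experiment(tab, "dependent", roster = roster, seed = 9)
  expect_identical(r1$summary, r2$summary)
  expect_length(r1$failures, 0)
  # averaged metric lies within per-evaluation min/max
  for (mod in c("lda", "decision_tree")) {
    det <- r1$detail[r1$detail$model == mod &
                       r1$detail$metric == "balanced_accuracy", "value"]
    avg <- r1$summary$value[r1$summary$model == mod &
                              r1$summary$metric == "balanced_accuracy"]
    expect_gte(avg, min(det))
    expect_lte(avg, max(det))
  }
})
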