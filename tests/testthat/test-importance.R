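# feature importance: raw scores, min-max scaling, rankings

test_that("minmax_scale follows the formula and its invariances", {
  expect_equal(unname(minmax_scale(c(2, 5, 8))), c(0, 0.5, 1))
  x <- c(3, 9, 4, 7)
  s <- minmax_scale(x)
  expect_equal(sum(s == 0), 1)
  expect_equal(sum(s == 1), 1)
  # affine invariance
  expect_equal(minmax_scale(2.5 * x + 11), s)
  flat <- minmax_scale(c(4, 4, 4))
  expect_equal(unname(flat), c(0, 0, 0), ignore_attr = TRUE)
  expect_true(attr(flat, "degenerate"))
  expect_error(minmax_scale(5), "at least 2")
})

test_that("the informative feature dominates raw scores in each family", {
  rows <- blob_rows(n = 80, gap = 5, seed = 13, extra_noise_feats = 3)
  rows$f2 <- rnorm(nrow(rows)) # keep a single informative feature, f1
  feats <- blob_feats(rows)
  for (fam in c("decision_tree", "random_forest", "logistic", "knn")) {
    model <- train_classifier(classifier_spec(fam, seed = 3), rows, feats)
    raw <- raw_importance(model, test_rows = rows, n_repeats = 10, seed = 5)
    expect_equal(names(which.max(raw)), "f1", info = fam)
  }
})

test_that("permutation importance of pure-noise features is near zero", {
  rows <- blob_rows(n = 100, gap = 5, seed = 21, extra_noise_feats = 2)
  feats <- blob_feats(rows)
  model <- train_classifier(classifier_spec("svm_rbf", seed = 1), rows, feats)
  raw <- raw_importance(model, test_rows = rows, n_repeats = 10, seed = 2)
  expect_lt(abs(raw[["noise1"]]), 0.02)
  expect_lt(abs(raw[["noise2"]]), 0.02)
  expect_error(raw_importance(model, test_rows = rows, n_repeats = 0),
               "n_repeats")
  expect_error(raw_importance(model, test_rows = NULL), "test rows")
})

test_that("rank_report orders by consensus with documented tie-breaks", {
  imp <- rbind(
    data.frame(model = "a", feature = c("x", "y", "z"), raw = c(1, 2, 3),
               scaled = c(0, 0.5, 1)),
    data.frame(model = "b", feature = c("x", "y", "z"), raw = c(10, 20, 30),
               scaled = c(0, 0.5, 1)))
  rep <- rank_report(imp, k = 2)
  expect_equal(rep$top_k, c("z", "y"))
  expect_equal(rep$consensus$mean_scaled, c(1, 0.5, 0))
  # identical raw scores across models -> identical rankings
  pm <- split(rep$per_model, rep$per_model$model)
  expect_equal(pm$a$feature, pm$b$feature)
  # tie-break by feature name
  tie <- data.frame(model = "a", feature = c("b", "a"), raw = c(1, 1),
                    scaled = c(1, 1))
  tie <- rbind(tie, data.frame(model = "b", feature = c("b", "a"),
                               raw = c(0, 1), scaled = c(0, 1)))
  expect_equal(rank_report(tie, k = 1)$top_k, "a")
  bad <- imp
  bad$feature[1] <- "w"
  expect_error(rank_report(bad), "mismatched")
})

test_that("permutation importance is reproducible under its seed", {
  rows <- blob_rows(n = 60, gap = 3, seed = 8)
  feats <- blob_feats(rows)
  model <- train_classifier(classifier_spec("knn"), rows, feats)
  a <- permutation_importance(model, rows, n_repeats = 5, seed = 11)
  b <- permutation_importance(model, rows, n_repeats = 5, seed = 11)
  expect_identical(a, b)
})
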