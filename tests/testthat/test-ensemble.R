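test_that("stratified splits are sized, disjoint, exhaustive and seeded", {
  ds <- tiny_training_set(seed = 31)  # 120 pos + 120 neg
  parts <- split_dataset(ds, 0.3, seed = 2)
  expect_length(parts$test$y, 72)
  expect_length(parts$train$y, 168)
  expect_equal(sum(parts$test$y), 36)  # class proportions preserved
  expect_length(intersect(parts$train$ids, parts$test$ids), 0)
  expect_setequal(c(parts$train$ids, parts$test$ids), ds$ids)
  again <- split_dataset(ds, 0.3, seed = 2)
  expect_identical(parts$test$ids, again$test$ids)
  other <- split_dataset(ds, 0.3, seed = 3)
  expect_false(identical(parts$test$ids, other$test$ids))
})

test_that("a four-sample balanced split puts one of each class per side", {
  x <- matrix(rnorm(8), 4, dimnames = list(NULL, c("u", "v")))
  ds <- labelled_dataset(x, c(TRUE, TRUE, FALSE, FALSE))
  parts <- split_dataset(ds, 0.5, seed = 1)
  expect_equal(sum(parts$test$y), 1)
  expect_equal(sum(parts$train$y), 1)
  expect_error(split_dataset(labelled_dataset(x, c(TRUE, FALSE, FALSE, FALSE)),
                             0.5, seed = 1), "fewer than 2")
})

test_that("confusion-matrix metrics satisfy their identities", {
  m <- metrics_from_confusion(748, 3, 10, 775)
  # weighted recall equals accuracy
  expect_equal(m$recall, m$accuracy)
  expect_true(all(unlist(m[c("accuracy", "precision", "recall", "f1")]) >= 0))
  expect_true(all(unlist(m[c("accuracy", "precision", "recall", "f1")]) <= 1))
  # against an independent support-weighted computation
  w_prec <- (758 * (748 / 751) + 778 * (775 / 785)) / 1536
  expect_equal(m$precision, w_prec)
  # swapping the classes swaps the per-class metrics
  sw <- metrics_from_confusion(775, 10, 3, 748)
  expect_equal(sw$per_class$positive$precision, m$per_class$negative$precision)
  expect_equal(sw$per_class$negative$recall, m$per_class$positive$recall)
  expect_equal(sw$accuracy, m$accuracy)
  # perfect classifier
  perf <- metrics_from_confusion(10, 0, 0, 20)
  expect_equal(unlist(perf[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  expect_warning(metrics_from_confusion(0, 0, 5, 5), "zero denominator")
})

test_that("rank AUC matches brute force and an independent package", {
  set.seed(9)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    scores <- round(rnorm(n), 1)  # rounding forces ties
    a <- auc_score(scores, labels)
    expect_equal(a, brute_force_auc(scores, labels))
    proc <- suppressMessages(pROC::auc(pROC::roc(labels, scores,
                                                 direction = "<", quiet = TRUE)))
    expect_equal(a, as.numeric(proc))
  }
  expect_error(auc_score(1:3, c(TRUE, TRUE, TRUE)), "single class")
  # label inversion maps AUC to 1 - AUC
  labels <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  scores <- c(3, 2.5, 1, 2, 0.5)
  expect_equal(auc_score(scores, !labels), 1 - auc_score(scores, labels))
})

test_that("every registry family separates an easy two-feature toy problem", {
  toy <- separable_toy(n_per_class = 40, seed = 4)
  parts <- split_dataset(toy, 0.3, seed = 1)
  for (fam in model_families()) {
    m <- train_model(model_spec(fam, seed = 7), parts$train)
    e <- evaluate(m, parts$test)
    expect_gte(e$accuracy, 0.95)
    expect_gte(e$auc_roc, 0.99)
  }
})

test_that("training is deterministic for a fixed seed", {
  toy <- separable_toy(n_per_class = 30, seed = 6)
  parts <- split_dataset(toy, 0.3, seed = 1)
  for (fam in c("gradient_boosting", "svm", "mlp", "knn")) {
    m1 <- train_model(model_spec(fam, seed = 12), parts$train)
    m2 <- train_model(model_spec(fam, seed = 12), parts$train)
    expect_identical(m1$config, m2$config)
    expect_identical(predict(m1, parts$test$x, type = "score"),
                     predict(m2, parts$test$x, type = "score"))
  }
})

test_that("a constant-feature dataset yields the majority-class no-information bound", {
  x <- matrix(1, 60, 2, dimnames = list(NULL, c("u", "v")))
  y <- rep(c(TRUE, FALSE), c(20, 40))
  ds <- labelled_dataset(x, y)
  m <- train_model(model_spec("logistic_regression", seed = 1), ds)
  # all-negative predictions make positive precision 0/0, reported as 0
  expect_warning(e <- evaluate(m, ds), "zero denominator")
  expect_equal(e$accuracy, 2 / 3)  # predicts the majority class throughout
  expect_true(all(!predict(m, ds$x, type = "class")))
})

test_that("cross-validation is seeded and reproduces its prefix", {
  toy <- separable_toy(n_per_class = 25, seed = 3)
  cv5 <- cross_validate(model_spec("lda", seed = 1), toy,
                        iterations = 5, seed = 21)
  expect_length(cv5$accuracies, 5)
  expect_equal(cv5$mean, 1)
  expect_equal(cv5$sd, 0)
  cv10 <- cross_validate(model_spec("lda", seed = 1), toy,
                         iterations = 10, seed = 21)
  expect_equal(cv10$accuracies[1:5], cv5$accuracies)
})

test_that("the trained core has eight members in fixed order and votes coherently", {
  fx <- tiny_ensemble()
  ens <- fx$ensemble
  expect_s3_class(ens, "nabh_ensemble")
  expect_identical(names(ens$members), core_families())
  expect_identical(ens$feature_order, feature_names())
  votes <- predict_votes(ens, fx$parts$test$x)
  expect_equal(dim(votes), c(length(fx$parts$test$y), 8L))
  pred <- nabh_predict(ens, fx$parts$test$x)
  expect_equal(pred$nabh_index, rowMeans(votes))
  # the core should learn the tiny benchmark well
  accs <- vapply(ens$members, function(m) {
    evaluate(m, fx$parts$test)$accuracy
  }, 0)
  expect_true(all(accs >= 0.85))
})

test_that("bundles round-trip through disk with identical predictions", {
  fx <- tiny_ensemble()
  dir <- withr::local_tempdir()
  save_bundle(fx$ensemble, dir)
  expect_true(file.exists(file.path(dir, "manifest.txt")))
  back <- load_bundle(dir)
  probe <- fx$parts$test$x[1:20, , drop = FALSE]
  expect_identical(predict_votes(back, probe), predict_votes(fx$ensemble, probe))
  # a different scale configuration must be refused
  cfg2 <- scale_config()
  cfg2$scales$redox["C"] <- 0.99
  expect_error(load_bundle(dir, config = cfg2), "scale configuration")
})
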