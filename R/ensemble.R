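# Classifier registry and training machinery: labelled datasets, stratified
# splits, per-family fitting with small hyperparameter grids, evaluation
# metrics and repeated cross-validation. The eight-member core (gradient
# boosting, SVM, AdaBoost, logistic regression, stacking, random forest,
# bagging, MLP) feeds the consensus index; six further families complete
# the registry for model comparison.

#' Labelled feature dataset
#'
#' @param x Numeric feature matrix with column names (one row per peptide).
#' @param y Logical labels (`TRUE` = nucleic-acid-binding helix).
#' @param ids Optional provenance strings, one per row.
#' @return A list of class `labelled_dataset` with elements `x`, `y`, `ids`.
#' @export
labelled_dataset <- function(x, y, ids = NULL) {
  x <- as.matrix(x)
  y <- as.logical(y)
  stopifnot(nrow(x) == length(y), !is.null(colnames(x)))
  if (is.null(ids)) ids <- sprintf("s%05d", seq_len(nrow(x)))
  stopifnot(length(ids) == nrow(x))
  structure(list(x = x, y = y, ids = as.character(ids)),
            class = "labelled_dataset")
}

#' @method print labelled_dataset
#' @export
print.labelled_dataset <- function(x, ...) {
  cat(sprintf("labelled_dataset: %d samples x %d features (%d positive, %d negative)\n",
              nrow(x$x), ncol(x$x), sum(x$y), sum(!x$y)))
  invisible(x)
}

#' @noRd
subset_dataset <- function(data, idx) {
  labelled_dataset(data$x[idx, , drop = FALSE], data$y[idx], data$ids[idx])
}

#' Stratified train/test split
#'
#' Splits the dataset into disjoint, exhaustive train and test parts,
#' preserving class proportions (the test size per class is
#' `round(n_class * test_fraction)`). Deterministic for a fixed seed.
#'
#' @param data A [labelled_dataset()].
#' @param test_fraction Fraction held out for testing, in (0, 1).
#' @param seed Integer seed.
#' @return A list with elements `train` and `test`, both
#'   [labelled_dataset()]s.
#' @export
split_dataset <- function(data, test_fraction = 0.3, seed = 1) {
  stopifnot(inherits(data, "labelled_dataset"),
            test_fraction > 0, test_fraction < 1)
  for (lbl in c(TRUE, FALSE)) {
    if (sum(data$y == lbl) < 2) {
      stop("class ", lbl, " has fewer than 2 members; cannot split")
    }
  }
  test_idx <- with_rseed(derive_seed(seed, "split"), {
    unlist(lapply(c(TRUE, FALSE), function(lbl) {
      members <- which(data$y == lbl)
      sample(members, round(length(members) * test_fraction))
    }))
  })
  test_idx <- sort(test_idx)
  list(train = subset_dataset(data, setdiff(seq_along(data$y), test_idx)),
       test = subset_dataset(data, test_idx))
}

#' Registry of classifier families
#'
#' @return Character vector of the 14 supported family names.
#' @export
model_families <- function() {
  c("gradient_boosting", "svm", "ada_boost", "logistic_regression", "ridge",
    "stacking", "random_forest", "bagging", "mlp", "naive_bayes",
    "bernoulli_nb", "lda", "qda", "knn")
}

#' The eight-member classifier core, in fixed order
#'
#' @return Character vector of the 8 core family names.
#' @export
core_families <- function() {
  c("gradient_boosting", "svm", "ada_boost", "logistic_regression",
    "stacking", "random_forest", "bagging", "mlp")
}

# Families whose features are z-scored (fit on the training split only);
# tree ensembles consume raw features.
.SCALED_FAMILIES <- c("svm", "logistic_regression", "ridge", "mlp", "knn")

#' Default hyperparameter grid for a family
#'
#' Modest grids sized for single-CPU training; override any of them through
#' [model_spec()].
#'
#' @param family One of [model_families()].
#' @return Named list of candidate values.
#' @export
default_grid <- function(family) {
  switch(match.arg(family, model_families()),
    gradient_boosting   = list(nrounds = c(100, 300), max_depth = 3, eta = 0.1),
    svm                 = list(cost = c(0.1, 1, 10), kernel = c("radial", "linear")),
    ada_boost           = list(n_rounds = c(50, 100), max_depth = 1),
    logistic_regression = list(maxit = 100),
    ridge               = list(lambda = c(0.001, 0.01, 0.1)),
    stacking            = list(meta = "logistic"),
    random_forest       = list(num_trees = c(100, 300)),
    bagging             = list(num_trees = c(100, 300)),
    mlp                 = list(size = c(16, 32), decay = 0.01, maxit = 150),
    naive_bayes         = list(laplace = 0),
    bernoulli_nb        = list(alpha = c(0.5, 1)),
    lda                 = list(tol = 1e-4),
    qda                 = list(tol = 1e-4),
    knn                 = list(k = c(3, 5, 11))
  )
}

#' Model specification
#'
#' @param family One of [model_families()].
#' @param grid Named list of hyperparameter candidates; defaults to
#'   [default_grid()] for the family. Must be non-empty.
#' @param seed Integer seed governing fold assignment and fit randomness.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(family, grid = NULL, seed = 1) {
  family <- match.arg(family, model_families())
  grid <- grid %||% default_grid(family)
  stopifnot(is.list(grid), length(grid) > 0)
  structure(list(family = family, grid = grid, seed = as.integer(seed)),
            class = "model_spec")
}

# ---- family fitting -------------------------------------------------------

#' @noRd
.fit_scaler <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

#' @noRd
.apply_scaler <- function(scaler, x) {
  if (is.null(scaler)) return(x)
  sweep(sweep(x, 2, scaler$center, "-"), 2, scaler$scale, "/")
}

# data.frame view with syntactic column names, for formula/data.frame-based
# learners (rpart, naiveBayes).
#' @noRd
.as_fdf <- function(x) {
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(x)))
  df
}

#' @noRd
.fit_family <- function(family, x, y, config, seed) {
  yf <- factor(y, levels = c("FALSE", "TRUE"))
  switch(family,
    gradient_boosting = {
      dtrain <- xgboost::xgb.DMatrix(x, label = as.numeric(y))
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = config$max_depth, eta = config$eta,
                      nthread = 1),
        data = dtrain, nrounds = config$nrounds, verbose = 0)
    },
    svm = {
      fit <- e1071::svm(x = x, y = yf, kernel = config$kernel,
                        cost = config$cost, scale = FALSE)
      dv <- attr(stats::predict(fit, x, decision.values = TRUE),
                 "decision.values")
      # orient the decision value so positive margin means class TRUE
      flip <- identical(colnames(dv), "FALSE/TRUE")
      list(fit = fit, flip = flip)
    },
    ada_boost = .fit_adaboost(x, y, n_rounds = config$n_rounds,
                              max_depth = config$max_depth),
    logistic_regression = {
      fit <- suppressWarnings(stats::glm.fit(
        cbind(`(Intercept)` = 1, x), as.numeric(y),
        family = stats::binomial(),
        control = list(maxit = config$maxit %||% 100)))
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      beta
    },
    ridge = glmnet::glmnet(x, yf, family = "binomial", alpha = 0,
                           lambda = config$lambda, standardize = FALSE),
    stacking = .fit_stacking(x, y, seed),
    random_forest = ranger::ranger(
      x = x, y = yf, num.trees = config$num_trees, probability = TRUE,
      seed = seed, num.threads = 1),
    bagging = ranger::ranger(
      x = x, y = yf, num.trees = config$num_trees, mtry = ncol(x),
      probability = TRUE, seed = seed, num.threads = 1),
    mlp = nnet::nnet(x = x, y = as.numeric(y), size = config$size,
                     decay = config$decay %||% 0.01,
                     maxit = config$maxit %||% 150,
                     entropy = TRUE, trace = FALSE, MaxNWts = 10000),
    naive_bayes = e1071::naiveBayes(x = .as_fdf(x), y = yf,
                                    laplace = config$laplace %||% 0),
    bernoulli_nb = .fit_bernoulli_nb(x, y, alpha = config$alpha %||% 1),
    lda = MASS::lda(x, grouping = yf, tol = config$tol %||% 1e-4),
    qda = MASS::qda(x, grouping = yf, tol = config$tol %||% 1e-4),
    knn = list(x = x, y = y, k = config$k),
    stop("unknown family: ", family)
  )
}

# Probability-like decision score in [0, 1]; class call is score >= 0.5.
#' @noRd
.score_family <- function(family, fit, x) {
  switch(family,
    gradient_boosting = as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(x))),
    svm = {
      dv <- attr(stats::predict(fit$fit, x, decision.values = TRUE),
                 "decision.values")
      s <- as.numeric(dv)
      if (fit$flip) s <- -s
      stats::plogis(s)
    },
    ada_boost = .score_adaboost(fit, x),
    logistic_regression = as.numeric(stats::plogis(
      cbind(1, x) %*% fit)),
    ridge = as.numeric(stats::plogis(
      stats::predict(fit, newx = x, type = "link")[, 1])),
    stacking = .score_stacking(fit, x),
    random_forest = ,
    bagging = as.numeric(stats::predict(fit, data = x,
                                        num.threads = 1)$predictions[, "TRUE"]),
    mlp = as.numeric(stats::predict(fit, x)),
    naive_bayes = as.numeric(stats::predict(fit, .as_fdf(x),
                                            type = "raw")[, "TRUE"]),
    bernoulli_nb = .score_bernoulli_nb(fit, x),
    lda = ,
    qda = as.numeric(stats::predict(fit, x)$posterior[, "TRUE"]),
    knn = {
      pred <- class::knn(train = fit$x, test = x,
                         cl = factor(fit$y, levels = c("FALSE", "TRUE")),
                         k = fit$k, prob = TRUE)
      p <- attr(pred, "prob")
      ifelse(pred == "TRUE", p, 1 - p)
    },
    stop("unknown family: ", family)
  )
}

# AdaBoost (SAMME, binary) over rpart stumps.
#' @noRd
.fit_adaboost <- function(x, y, n_rounds = 100, max_depth = 1) {
  df <- .as_fdf(x)
  df$.y <- factor(y, levels = c("FALSE", "TRUE"))
  n <- nrow(df)
  w <- rep(1 / n, n)
  trees <- list()
  alphas <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = max_depth, cp = 0, minsplit = 10,
                               xval = 0)
  for (m in seq_len(n_rounds)) {
    tr <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                       control = ctrl)
    pred <- stats::predict(tr, df, type = "class")
    miss <- pred != df$.y
    err <- sum(w[miss]) / sum(w)
    if (err >= 0.5 && m > 1) break
    err <- min(max(err, 1e-10), 1 - 1e-10)
    a <- log((1 - err) / err)
    trees[[length(trees) + 1]] <- tr
    alphas <- c(alphas, a)
    w <- w * exp(a * miss)
    w <- w / sum(w)
    if (err <= 1e-10) break
  }
  list(trees = trees, alphas = alphas)
}

#' @noRd
.score_adaboost <- function(fit, x) {
  df <- .as_fdf(x)
  margin <- rep(0, nrow(df))
  for (m in seq_along(fit$trees)) {
    pred <- stats::predict(fit$trees[[m]], df, type = "class")
    margin <- margin + fit$alphas[m] * ifelse(pred == "TRUE", 1, -1)
  }
  stats::plogis(margin / max(sum(abs(fit$alphas)), 1e-10) * 8)
}

# Bernoulli naive Bayes on median-binarized features.
#' @noRd
.fit_bernoulli_nb <- function(x, y, alpha = 1) {
  thr <- apply(x, 2, stats::median)
  xb <- sweep(x, 2, thr, ">")
  n1 <- sum(y); n0 <- sum(!y)
  p1 <- (colSums(xb[y, , drop = FALSE]) + alpha) / (n1 + 2 * alpha)
  p0 <- (colSums(xb[!y, , drop = FALSE]) + alpha) / (n0 + 2 * alpha)
  list(thr = thr, p1 = p1, p0 = p0,
       prior1 = n1 / (n1 + n0), prior0 = n0 / (n1 + n0))
}

#' @noRd
.score_bernoulli_nb <- function(fit, x) {
  xb <- sweep(x, 2, fit$thr, ">")
  ll1 <- xb %*% log(fit$p1) + (!xb) %*% log(1 - fit$p1) + log(fit$prior1)
  ll0 <- xb %*% log(fit$p0) + (!xb) %*% log(1 - fit$p0) + log(fit$prior0)
  as.numeric(stats::plogis(ll1 - ll0))
}

# Stacking: the seven other core families as base learners (first default
# configuration each), 3-fold out-of-fold probability features, logistic
# meta-learner, bases refitted on the full data.
#' @noRd
.stacking_bases <- function() setdiff(core_families(), "stacking")

#' @noRd
.first_config <- function(family) {
  lapply(default_grid(family), `[`, 1)
}

#' @noRd
.fit_stacking <- function(x, y, seed) {
  bases <- .stacking_bases()
  k <- 3
  folds <- .stratified_folds(y, k, derive_seed(seed, "stack-folds"))
  z <- matrix(NA_real_, nrow(x), length(bases),
              dimnames = list(NULL, bases))
  for (f in seq_len(k)) {
    tr <- folds != f
    for (b in bases) {
      sub <- with_rseed(derive_seed(seed, "stack", b, f), {
        .fit_config(b, x[tr, , drop = FALSE], y[tr], .first_config(b),
                    derive_seed(seed, "stack", b, f))
      })
      z[!tr, b] <- .score_model(sub, x[!tr, , drop = FALSE])
    }
  }
  meta <- suppressWarnings(stats::glm.fit(
    cbind(1, z), as.numeric(y), family = stats::binomial()))
  beta <- meta$coefficients
  beta[is.na(beta)] <- 0
  full <- lapply(bases, function(b) {
    .fit_config(b, x, y, .first_config(b), derive_seed(seed, "stack-full", b))
  })
  names(full) <- bases
  list(bases = full, beta = beta)
}

#' @noRd
.score_stacking <- function(fit, x) {
  z <- vapply(fit$bases, function(b) .score_model(b, x), numeric(nrow(x)))
  if (nrow(x) == 1) z <- matrix(z, nrow = 1)
  as.numeric(stats::plogis(cbind(1, z) %*% fit$beta))
}

# ---- config-level fit / predict -------------------------------------------

#' @noRd
.fit_config <- function(family, x, y, config, seed) {
  scaler <- if (family %in% .SCALED_FAMILIES) .fit_scaler(x) else NULL
  xs <- .apply_scaler(scaler, x)
  fit <- with_rseed(seed, .fit_family(family, xs, y, config, seed))
  structure(list(family = family, config = config, scaler = scaler,
                 fit = fit, feature_order = colnames(x), seed = seed),
            class = "nabh_model")
}

#' @noRd
.score_model <- function(model, x) {
  xs <- .apply_scaler(model$scaler, x)
  .score_family(model$family, model$fit, xs)
}

#' Predict with a fitted model
#'
#' @param object A fitted `nabh_model` from [train_model()].
#' @param newdata Feature matrix with the model's feature columns.
#' @param type `"class"` for logical calls (score >= 0.5) or `"score"` for
#'   the probability-like decision score in `[0, 1]`.
#' @param ... Unused.
#' @return Logical or numeric vector, one value per row.
#' @export
predict.nabh_model <- function(object, newdata,
                               type = c("class", "score"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!identical(colnames(newdata), object$feature_order)) {
    if (all(object$feature_order %in% colnames(newdata))) {
      newdata <- newdata[, object$feature_order, drop = FALSE]
    } else {
      stop("feature columns do not match the model's feature order")
    }
  }
  s <- .score_model(object, newdata)
  if (type == "score") s else s >= 0.5
}

#' @method print nabh_model
#' @export
print.nabh_model <- function(x, ...) {
  cat("nabh_model:", x$family, "\n  config:",
      paste(names(x$config), unlist(x$config), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

# ---- grid search ----------------------------------------------------------

#' @noRd
.stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  with_rseed(seed, {
    for (lbl in c(TRUE, FALSE)) {
      members <- which(y == lbl)
      folds[members] <- sample(rep(seq_len(k), length.out = length(members)))
    }
  })
  folds
}

#' Train one classifier with grid search
#'
#' Expands the spec's hyperparameter grid, scores every configuration by
#' 3-fold stratified cross-validated accuracy on the training data, picks
#' the winner (ties break to the first configuration in grid order) and
#' refits it on the full training set. When the grid contains a single
#' configuration the selection step is skipped. Features are z-scored
#' (fitted on the training data only) for margin/distance-based families;
#' tree ensembles consume raw features. Deterministic for a fixed
#' `spec$seed`.
#'
#' @param spec A [model_spec()].
#' @param train A [labelled_dataset()] containing both classes.
#' @return A fitted `nabh_model`, with the grid-search table in `$cv_table`
#'   and the winning configuration in `$config`.
#' @export
train_model <- function(spec, train) {
  stopifnot(inherits(spec, "model_spec"), inherits(train, "labelled_dataset"))
  if (!any(train$y) || !any(!train$y)) stop("training data needs both classes")
  configs <- expand.grid(spec$grid, stringsAsFactors = FALSE)
  cv_table <- NULL
  best <- 1L
  if (nrow(configs) > 1) {
    k <- 3
    folds <- .stratified_folds(train$y, k, derive_seed(spec$seed, "gridcv"))
    for (f in seq_len(k)) {
      ytr <- train$y[folds != f]
      if (!any(ytr) || !any(!ytr)) {
        stop(sprintf("fold %d of %d is single-class (%d pos / %d neg in fold train)",
                     f, k, sum(ytr), sum(!ytr)))
      }
    }
    acc <- matrix(NA_real_, nrow(configs), k)
    for (ci in seq_len(nrow(configs))) {
      config <- lapply(configs, function(col) col[ci])
      for (f in seq_len(k)) {
        tr <- folds != f
        m <- .fit_config(spec$family, train$x[tr, , drop = FALSE],
                         train$y[tr], config,
                         derive_seed(spec$seed, "grid", ci, f))
        pred <- .score_model(m, train$x[!tr, , drop = FALSE]) >= 0.5
        acc[ci, f] <- mean(pred == train$y[!tr])
      }
    }
    mean_acc <- rowMeans(acc)
    best <- which.max(mean_acc)  # ties -> first config
    cv_table <- cbind(configs, cv_accuracy = mean_acc)
  }
  config <- lapply(configs, function(col) col[best])
  model <- .fit_config(spec$family, train$x, train$y, config,
                       derive_seed(spec$seed, "fit"))
  model$cv_table <- cv_table
  model$spec_seed <- spec$seed
  model
}

# ---- metrics --------------------------------------------------------------

#' Classification metrics from a confusion matrix
#'
#' Computes accuracy and support-weighted precision, recall and F1 from the
#' four confusion-matrix cells, with the class supports `TP + FN`
#' (positive) and `FP + TN` (negative). Weighted recall equals accuracy by
#' construction. Per-class metrics with a zero denominator are defined as 0
#' with a warning.
#'
#' @param TP,FP,FN,TN Non-negative integer cell counts (layout
#'   `[[TP, FP], [FN, TN]]`).
#' @return A list of class `metrics_report` with elements `TP`, `FP`, `FN`,
#'   `TN`, `accuracy`, `precision`, `recall`, `f1` (weighted averages) and
#'   `per_class`.
#' @export
#' @examples
#' metrics_from_confusion(748, 3, 10, 775)$accuracy  # 0.99154...
metrics_from_confusion <- function(TP, FP, FN, TN) {
  stopifnot(TP >= 0, FP >= 0, FN >= 0, TN >= 0)
  total <- TP + FP + FN + TN
  if (total == 0) stop("empty confusion matrix")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning("zero denominator for ", what, "; defining it as 0")
      return(0)
    }
    num / den
  }
  prec_pos <- safe_div(TP, TP + FP, "positive precision")
  prec_neg <- safe_div(TN, TN + FN, "negative precision")
  rec_pos <- safe_div(TP, TP + FN, "positive recall")
  rec_neg <- safe_div(TN, TN + FP, "negative recall")
  f1_of <- function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r)
  sup_pos <- TP + FN
  sup_neg <- FP + TN
  wavg <- function(a, b) (sup_pos * a + sup_neg * b) / total
  structure(list(
    TP = TP, FP = FP, FN = FN, TN = TN,
    accuracy = (TP + TN) / total,
    precision = wavg(prec_pos, prec_neg),
    recall = wavg(rec_pos, rec_neg),
    f1 = wavg(f1_of(prec_pos, rec_pos), f1_of(prec_neg, rec_neg)),
    auc_roc = NA_real_,
    per_class = list(
      positive = list(precision = prec_pos, recall = rec_pos,
                      f1 = f1_of(prec_pos, rec_pos), support = sup_pos),
      negative = list(precision = prec_neg, recall = rec_neg,
                      f1 = f1_of(prec_neg, rec_neg), support = sup_neg))
  ), class = "metrics_report")
}

#' @method print metrics_report
#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("metrics_report: accuracy %.4f, precision %.4f, ",
                     "recall %.4f, F1 %.4f, AUC %.4f\n",
                     "  confusion [[TP=%d, FP=%d], [FN=%d, TN=%d]]\n"),
              x$accuracy, x$precision, x$recall, x$f1, x$auc_roc,
              x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative, with ties counted half.
#'
#' @param scores Numeric decision scores.
#' @param labels Logical labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC undefined: test labels contain a single class")
  }
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Evaluate a fitted model on a test set
#'
#' Hard calls (score >= 0.5) build the confusion matrix; metrics come from
#' [metrics_from_confusion()]; AUC-ROC from the decision scores via
#' [auc_score()].
#'
#' @param model A fitted `nabh_model`.
#' @param test A [labelled_dataset()] containing both classes.
#' @return A `metrics_report`.
#' @export
evaluate <- function(model, test) {
  stopifnot(inherits(model, "nabh_model"), inherits(test, "labelled_dataset"))
  scores <- stats::predict(model, test$x, type = "score")
  pred <- scores >= 0.5
  rep <- metrics_from_confusion(
    TP = sum(pred & test$y), FP = sum(pred & !test$y),
    FN = sum(!pred & test$y), TN = sum(!pred & !test$y))
  rep$auc_roc <- auc_score(scores, test$y)
  rep
}

#' Repeated cross-validation of a model specification
#'
#' Repeated stratified shuffle-split validation: each iteration draws a
#' fresh 70/30 split, trains the specification on the training part
#' (including its grid search) and records test accuracy. Iteration seeds
#' are derived independently from the top-level seed, so extending
#' `iterations` reproduces the earlier iterations' scores.
#'
#' @param spec A [model_spec()].
#' @param data A [labelled_dataset()].
#' @param iterations Number of shuffle-split iterations (>= 2).
#' @param seed Integer seed.
#' @param test_fraction Held-out fraction per iteration.
#' @return A list with `mean`, `sd`, `accuracies` and `iterations`.
#' @export
cross_validate <- function(spec, data, iterations = 50, seed = 1,
                           test_fraction = 0.3) {
  stopifnot(inherits(spec, "model_spec"), iterations >= 2)
  accs <- vapply(seq_len(iterations), function(i) {
    it_seed <- derive_seed(seed, "cv-iter", i)
    parts <- split_dataset(data, test_fraction, seed = it_seed)
    it_spec <- model_spec(spec$family, grid = spec$grid, seed = it_seed)
    m <- train_model(it_spec, parts$train)
    evaluate(m, parts$test)$accuracy
  }, 0)
  list(mean = mean(accs), sd = stats::sd(accs), accuracies = accs,
       iterations = iterations)
}

# ---- ensemble -------------------------------------------------------------

#' Train the classifier core as an ensemble
#'
#' Trains one model per family (default: the eight-member core in its fixed
#' order) via [train_model()], each with a seed derived from the top-level
#' seed. The returned ensemble carries the canonical feature order and the
#' grid winners, and feeds [nabh_predict()].
#'
#' @param train A [labelled_dataset()].
#' @param seed Integer top-level seed.
#' @param families Families to include, in order.
#' @param grids Optional named list of grid overrides per family.
#' @return A list of class `nabh_ensemble` with elements `members` (named
#'   list of `nabh_model`s in order), `feature_order`, `seed`, `metadata`.
#' @export
train_ensemble <- function(train, seed = 1, families = core_families(),
                           grids = NULL) {
  stopifnot(inherits(train, "labelled_dataset"))
  members <- lapply(families, function(fam) {
    spec <- model_spec(fam, grid = grids[[fam]] %||% NULL,
                       seed = derive_seed(seed, "member", fam))
    train_model(spec, train)
  })
  names(members) <- families
  structure(list(
    members = members,
    feature_order = colnames(train$x),
    seed = as.integer(seed),
    metadata = list(
      n_members = length(members),
      grid_winners = lapply(members, function(m) m$config),
      n_train = nrow(train$x))
  ), class = "nabh_ensemble")
}

#' @method print nabh_ensemble
#' @export
print.nabh_ensemble <- function(x, ...) {
  cat(sprintf("nabh_ensemble: %d members (%s); %d features; seed %d\n",
              length(x$members), paste(names(x$members), collapse = ", "),
              length(x$feature_order), x$seed))
  invisible(x)
}

#' Per-member boolean votes
#'
#' @param ensemble A trained `nabh_ensemble`.
#' @param x Feature matrix in the ensemble's feature order.
#' @return Logical matrix, one row per sample, one column per member in
#'   fixed member order.
#' @export
predict_votes <- function(ensemble, x) {
  stopifnot(inherits(ensemble, "nabh_ensemble"))
  x <- as.matrix(x)
  if (!identical(colnames(x), ensemble$feature_order)) {
    stop("feature columns do not match the ensemble's feature order")
  }
  votes <- vapply(ensemble$members,
                  function(m) stats::predict(m, x, type = "class"),
                  logical(nrow(x)))
  if (nrow(x) == 1) votes <- matrix(votes, nrow = 1,
                                    dimnames = list(NULL, names(ensemble$members)))
  votes
}
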