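# Permutation feature relevance averaged over the ensemble, and the
# feature-saturation curve (accuracy as a function of the number of
# top-ranked features).

#' Permutation feature relevance of an ensemble
#'
#' For every member model and feature, measures the mean drop in accuracy
#' when that feature column is randomly permuted (`repeats` draws), clips
#' negative drops at zero, averages the drops across members, and
#' normalizes to percentages summing to 100.
#'
#' @param ensemble A trained `nabh_ensemble`.
#' @param data A [labelled_dataset()] to measure accuracy on (typically the
#'   held-out test split).
#' @param seed Integer seed for the permutations.
#' @param repeats Permutations per feature per member.
#' @return A `data.frame` with columns `feature` and `relevance`
#'   (percentages, summing to 100), sorted by decreasing relevance.
#' @export
feature_relevance <- function(ensemble, data, seed = 1, repeats = 10) {
  stopifnot(inherits(ensemble, "nabh_ensemble"),
            inherits(data, "labelled_dataset"))
  x <- data$x
  y <- data$y
  p <- ncol(x)
  drops <- matrix(0, p, length(ensemble$members),
                  dimnames = list(colnames(x), names(ensemble$members)))
  for (mi in seq_along(ensemble$members)) {
    model <- ensemble$members[[mi]]
    base_acc <- mean(stats::predict(model, x, type = "class") == y)
    for (fi in seq_len(p)) {
      acc <- with_rseed(derive_seed(seed, "perm", mi, fi), {
        vapply(seq_len(repeats), function(r) {
          xp <- x
          xp[, fi] <- xp[sample.int(nrow(xp)), fi]
          mean(stats::predict(model, xp, type = "class") == y)
        }, 0)
      })
      drops[fi, mi] <- max(base_acc - mean(acc), 0)
    }
  }
  avg <- rowMeans(drops)
  if (sum(avg) == 0) {
    warning("no feature permutation changed any member's accuracy; ",
            "returning uniform relevance")
    avg <- rep(1, p)
  }
  rel <- 100 * avg / sum(avg)
  out <- data.frame(feature = colnames(x), relevance = rel,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$relevance), , drop = FALSE]
}

#' Combined share of the top-k relevance entries
#'
#' @param relevance A `data.frame` with columns `feature`, `relevance`
#'   (as from [feature_relevance()] or a published relevance table).
#' @param k Number of largest entries to sum.
#' @return Their summed percentage.
#' @export
relevance_top_share <- function(relevance, k = 3) {
  stopifnot(is.data.frame(relevance), "relevance" %in% names(relevance),
            k >= 1, k <= nrow(relevance))
  sum(sort(relevance$relevance, decreasing = TRUE)[seq_len(k)])
}

#' Feature-saturation curve
#'
#' Retrains each core family on the top-`k` features (for each `k` in
#' `k_range`, under the supplied feature ranking) and records held-out
#' accuracy. Each family is fitted at its first default configuration; the
#' per-`k` refits skip grid search for tractability.
#'
#' @param data A [labelled_dataset()].
#' @param k_range Integer vector of feature counts (within
#'   `2..ncol(data$x)`).
#' @param seed Integer seed (drives the split and the fits).
#' @param ranking Character vector of feature names, most relevant first.
#'   Default: impurity importance of a seeded random forest on the training
#'   split.
#' @param families Families to trace (default: the eight core families).
#' @param test_fraction Held-out fraction.
#' @return A `data.frame` with columns `k`, `family`, `accuracy`
#'   (`length(k_range) * length(families)` rows).
#' @export
feature_saturation <- function(data, k_range = 3:20, seed = 1, ranking = NULL,
                               families = core_families(),
                               test_fraction = 0.3) {
  stopifnot(inherits(data, "labelled_dataset"),
            all(k_range >= 2), all(k_range <= ncol(data$x)))
  parts <- split_dataset(data, test_fraction, seed = derive_seed(seed, "sat"))
  if (is.null(ranking)) {
    rf <- ranger::ranger(x = parts$train$x,
                         y = factor(parts$train$y, levels = c("FALSE", "TRUE")),
                         num.trees = 200, importance = "impurity",
                         seed = derive_seed(seed, "sat-rank"), num.threads = 1)
    ranking <- names(sort(rf$variable.importance, decreasing = TRUE))
  }
  stopifnot(all(ranking %in% colnames(data$x)))
  rows <- list()
  for (k in k_range) {
    keep <- ranking[seq_len(k)]
    tr_k <- labelled_dataset(parts$train$x[, keep, drop = FALSE],
                             parts$train$y, parts$train$ids)
    te_k <- labelled_dataset(parts$test$x[, keep, drop = FALSE],
                             parts$test$y, parts$test$ids)
    for (fam in families) {
      m <- .fit_config(fam, tr_k$x, tr_k$y, .first_config(fam),
                       derive_seed(seed, "sat-fit", fam, k))
      acc <- mean(stats::predict(m, te_k$x, type = "class") == te_k$y)
      rows[[length(rows) + 1]] <- data.frame(k = k, family = fam,
                                             accuracy = acc,
                                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Published average feature relevance of the eight-model classifier
#'
#' Loads the reference table of average feature-relevance percentages
#' reported for the published eight-model nucleic-acid-binding-helix
#' classifier, shipped with the package for comparison and arithmetic
#' checks (the top three entries account for 51.93% of total relevance).
#'
#' @return A `data.frame` with columns `feature` and `relevance`.
#' @export
published_relevance <- function() {
  path <- system.file("extdata", "published_feature_relevance.tsv",
                      package = "nabhelix", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
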