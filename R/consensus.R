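# Consensus scoring: the NABh index is the fraction of ensemble members
# voting positive, reported at three confidence tiers.

#' NABh consensus index
#'
#' The fraction of positive member predictions: the number of `TRUE` votes
#' divided by the total number of models. For an eight-member ensemble the
#' index lives on the nine-point lattice 0, 0.125, ..., 1; unanimity gives
#' 1.0, seven of eight 0.875, six of eight 0.75.
#'
#' @param votes Logical vector of per-member calls (length >= 1).
#' @return The index in `[0, 1]`.
#' @export
#' @examples
#' nabh_index(rep(TRUE, 8))                       # 1
#' nabh_index(c(rep(TRUE, 6), rep(FALSE, 2)))     # 0.75
nabh_index <- function(votes) {
  if (length(votes) == 0) stop("empty vote vector")
  votes <- as.logical(votes)
  if (anyNA(votes)) stop("votes must be TRUE/FALSE")
  sum(votes) / length(votes)
}

#' Confidence tier of an index value
#'
#' `"strong"` for a unanimous index of 1.0, `"likely"` for
#' `threshold <= index < 1`, `"unreliable"` below the reporting threshold
#' (default 0.75, i.e. six of eight members).
#'
#' @param index NABh index value(s) in `[0, 1]`.
#' @param threshold Reporting threshold.
#' @return Character vector over `{"strong", "likely", "unreliable"}`.
#' @export
#' @examples
#' classify_tier(c(1, 0.875, 0.625))
classify_tier <- function(index, threshold = 0.75) {
  if (any(index < 0 | index > 1)) stop("index must lie in [0, 1]")
  eps <- 1e-9
  ifelse(index >= 1 - eps, "strong",
         ifelse(index >= threshold - eps, "likely", "unreliable"))
}

#' Consensus predictions for a feature matrix
#'
#' Collects the per-member votes, the consensus index and the confidence
#' tier for every row.
#'
#' @param ensemble A trained `nabh_ensemble`.
#' @param x Feature matrix in the ensemble's feature order.
#' @param threshold Tier threshold passed to [classify_tier()].
#' @return A `data.frame` with one logical column per member, plus
#'   `nabh_index` and `tier`.
#' @export
nabh_predict <- function(ensemble, x, threshold = 0.75) {
  votes <- predict_votes(ensemble, x)
  idx <- rowMeans(votes)
  out <- as.data.frame(votes)
  out$nabh_index <- idx
  out$tier <- classify_tier(idx, threshold)
  out
}
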