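# Shared fixtures and independent oracles used across the suite.

# Brute-force helix scanner: enumerate every window, mark covered indices,
# split maximal runs. Kept deliberately naive and separate from the package
# implementation.
brute_force_helices <- function(sequence, residues = c("A", "E", "H", "K", "L", "M", "Q", "R"),
                                min_hits = 4, window = 6) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < window) return(data.frame(start = integer(0), end = integer(0)))
  covered <- rep(FALSE, n)
  for (s in 1:(n - window + 1)) {
    win <- chars[s:(s + window - 1)]
    if (sum(win %in% residues) >= min_hits) covered[s:(s + window - 1)] <- TRUE
  }
  starts <- integer(0); ends <- integer(0)
  i <- 1L
  while (i <= n) {
    if (covered[i]) {
      j <- i
      while (j < n && covered[j + 1]) j <- j + 1L
      starts <- c(starts, i - 1L); ends <- c(ends, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  data.frame(start = as.integer(starts), end = as.integer(ends),
             stringsAsFactors = FALSE)
}

# Brute-force AUC: all positive/negative score pairs, ties count half.
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

random_protein <- function(len) {
  paste(sample(nabhelix::amino_acids(), len, replace = TRUE), collapse = "")
}

# Small but learnable synthetic dataset (kept modest so per-test training
# stays fast).
tiny_training_set <- function(seed = 11) {
  generate_training_set(synthetic_spec(n_pos = 120, n_neg_albumin = 40,
                                       n_neg_random = 80, seed = seed))
}

# A two-feature, cleanly separable toy problem.
separable_toy <- function(n_per_class = 40, seed = 4, gap = 4) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(2 * n_per_class), ncol = 2),
             matrix(rnorm(2 * n_per_class, mean = gap), ncol = 2))
  colnames(x) <- c("u", "v")
  labelled_dataset(x, rep(c(FALSE, TRUE), each = n_per_class))
}

# One small trained ensemble shared across tests (training is the slow
# part; memoized per test run).
.fixture_env <- new.env(parent = emptyenv())

tiny_ensemble <- function() {
  if (is.null(.fixture_env$ens)) {
    ds <- tiny_training_set(seed = 11)
    parts <- split_dataset(ds, 0.3, seed = 11)
    .fixture_env$ens <- train_ensemble(parts$train, seed = 11)
    .fixture_env$parts <- parts
  }
  list(ensemble = .fixture_env$ens, parts = .fixture_env$parts)
}
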