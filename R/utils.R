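# Internal helpers: deterministic seed derivation and scoped RNG use.

#' @noRd
derive_seed <- function(seed, ...) {
  labels <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (code in utf8ToInt(labels)) h <- (h * 31 + code) %% 2147483647L
  as.integer(h) + 1L
}

# Evaluate `expr` under set.seed(seed) without disturbing the caller's RNG
# stream.
#' @noRd
with_rseed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# djb2 string hash, hex-encoded; used to fingerprint scale configurations in
# model-bundle manifests.
#' @noRd
djb2_hash <- function(x) {
  stopifnot(is.character(x))
  h <- 5381
  for (code in utf8ToInt(paste(x, collapse = "\x1f"))) {
    h <- (h * 33 + code) %% 4294967296
  }
  sprintf("%08x", h)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
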