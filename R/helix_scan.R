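# Composition-based helix detection: a hexamer window qualifies when at
# least four of its residues come from the helix-favouring set; candidate
# segments are maximal runs of indices covered by qualifying windows.

#' Helix-detection alphabet
#'
#' The residue set and window rule used by [extract_helices()]: a window of
#' `window` consecutive residues qualifies as helix-like when at least
#' `min_hits` of them belong to `residues`. Defaults are the eight
#' helix-favouring residues A, E, H, K, L, M, Q, R with 4-of-6 windows.
#'
#' @param residues Character vector of one-letter codes.
#' @param min_hits Minimum number of window positions that must come from
#'   `residues`.
#' @param window Window length.
#' @return A list of class `helix_alphabet`.
#' @export
#' @examples
#' helix_alphabet()
helix_alphabet <- function(residues = c("A", "E", "H", "K", "L", "M", "Q", "R"),
                           min_hits = 4, window = 6) {
  residues <- unique(toupper(residues))
  bad <- setdiff(residues, amino_acids())
  if (length(bad) > 0) {
    stop("non-standard residues in helix alphabet: ", paste(bad, collapse = ", "))
  }
  min_hits <- as.integer(min_hits)
  window <- as.integer(window)
  if (window < 1 || min_hits < 1 || min_hits > window) {
    stop("need 1 <= min_hits <= window")
  }
  structure(list(residues = residues, min_hits = min_hits, window = window),
            class = "helix_alphabet")
}

#' Does a window qualify as helix-like?
#'
#' @param hexamer A string of exactly `alphabet$window` residues.
#' @param alphabet A [helix_alphabet()].
#' @return `TRUE` iff at least `min_hits` residues of the window are in the
#'   alphabet's residue set.
#' @export
#' @examples
#' window_qualifies("KKKKGG")  # TRUE: 4 of 6
#' window_qualifies("KKKGGG")  # FALSE: 3 of 6
window_qualifies <- function(hexamer, alphabet = helix_alphabet()) {
  stopifnot(inherits(alphabet, "helix_alphabet"), is.character(hexamer),
            length(hexamer) == 1)
  if (nchar(hexamer) != alphabet$window) {
    stop("window must have length ", alphabet$window,
         ", got ", nchar(hexamer))
  }
  chars <- strsplit(toupper(hexamer), "", fixed = TRUE)[[1]]
  sum(chars %in% alphabet$residues) >= alphabet$min_hits
}

#' Extract candidate helical segments from one sequence
#'
#' Slides the window with step 1 over the sequence, takes the union of all
#' positions covered by qualifying windows, and reports each maximal run of
#' covered positions as one segment. Coordinates are 0-based, half-open
#' `[start, end)`. Sequences shorter than the window yield no segments.
#' Every returned segment has length >= `alphabet$window`, contains at
#' least one qualifying window, and segments are non-overlapping and sorted
#' by start.
#'
#' @param sequence A protein sequence string (standard residues).
#' @param id Parent-sequence identifier recorded in the output.
#' @param alphabet A [helix_alphabet()].
#' @return A `data.frame` with columns `parent_id`, `start`, `end`
#'   (0-based half-open) and `sequence`.
#' @export
#' @examples
#' extract_helices("KKKKKKGGGGGGKKKKKK", id = "demo")
extract_helices <- function(sequence, id = "query", alphabet = helix_alphabet()) {
  stopifnot(inherits(alphabet, "helix_alphabet"), is.character(sequence),
            length(sequence) == 1)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  w <- alphabet$window
  empty <- data.frame(parent_id = character(0), start = integer(0),
                      end = integer(0), sequence = character(0),
                      stringsAsFactors = FALSE)
  if (n < w) return(empty)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  hit <- as.integer(chars %in% alphabet$residues)
  # rolling window sums via cumulative sums
  cs <- c(0L, cumsum(hit))
  wsum <- cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]
  qstart <- which(wsum >= alphabet$min_hits)       # 1-based window starts
  if (length(qstart) == 0) return(empty)
  covered <- logical(n)
  for (s in qstart) covered[s:(s + w - 1)] <- TRUE
  runs <- rle(covered)
  ends1 <- cumsum(runs$lengths)
  starts1 <- ends1 - runs$lengths + 1
  keep <- runs$values
  starts1 <- starts1[keep]
  ends1 <- ends1[keep]
  stopifnot(all(ends1 - starts1 + 1 >= w))  # runs can never be shorter than a window
  data.frame(
    parent_id = rep(id, length(starts1)),
    start = as.integer(starts1 - 1L),
    end = as.integer(ends1),
    sequence = substring(sequence, starts1, ends1),
    stringsAsFactors = FALSE
  )
}

#' Extract helices across many records
#'
#' Applies [extract_helices()] to every row of a record table and binds the
#' results, preserving input record order.
#'
#' @param records A `data.frame` with columns `id` and `sequence` (as from
#'   [read_fasta()]).
#' @param alphabet A [helix_alphabet()].
#' @return A `data.frame` as in [extract_helices()].
#' @export
scan_proteins <- function(records, alphabet = helix_alphabet()) {
  stopifnot(is.data.frame(records))
  parts <- lapply(seq_len(nrow(records)), function(i) {
    extract_helices(records$sequence[i], id = records$id[i], alphabet = alphabet)
  })
  out <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- extract_helices("", id = "x", alphabet = alphabet)  # empty frame
  }
  out
}
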