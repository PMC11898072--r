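# FASTA input, record validation and CSV/FASTA output. Parsing itself is
# delegated to Biostrings; this layer enforces the 20-letter alphabet,
# unique ids and the id/description split.

#' Read a protein FASTA file
#'
#' Parses single- or multi-record FASTA (wrapped or unwrapped lines),
#' uppercases sequences, splits each header into an id (first whitespace
#' token) and a free-text description, and validates every sequence against
#' the 20 standard one-letter amino-acid codes. Duplicate ids and empty
#' files are errors.
#'
#' @param path Path to a FASTA file.
#' @param on_invalid What to do with a record containing a non-standard
#'   residue (e.g. B, J, O, U, X, Z, `*`) after uppercasing: `"error"`
#'   (default) aborts naming the record and the offending character,
#'   `"skip"` drops the whole record with a warning, `"strip"` removes the
#'   offending characters with a warning.
#' @return A `data.frame` with character columns `id`, `description`,
#'   `sequence`, one row per record, in file order.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 demo", "MKKL"), f)
#' read_fasta(f)
read_fasta <- function(path, on_invalid = c("error", "skip", "strip")) {
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0) stop("no records in FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(gsub("[ \t\r]", "", as.character(set)))
  if (any(ids == "")) stop("FASTA record with empty id")
  if (anyDuplicated(ids)) {
    stop("duplicate record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  records <- data.frame(id = ids, description = desc, sequence = seqs,
                        stringsAsFactors = FALSE, row.names = NULL)
  validate_records(records, on_invalid = on_invalid)
}

#' Validate protein records against the standard alphabet
#'
#' @param records A `data.frame` with columns `id`, `description`, `sequence`.
#' @inheritParams read_fasta
#' @return The validated (possibly filtered or stripped) `data.frame`.
#' @export
validate_records <- function(records, on_invalid = c("error", "skip", "strip")) {
  on_invalid <- match.arg(on_invalid)
  stopifnot(is.data.frame(records),
            all(c("id", "sequence") %in% names(records)))
  if (!("description" %in% names(records))) records$description <- ""
  records$sequence <- toupper(records$sequence)
  pattern <- paste0("[^", paste(amino_acids(), collapse = ""), "]")
  bad_chr <- regmatches(records$sequence, regexpr(pattern, records$sequence))
  has_bad <- grepl(pattern, records$sequence)
  if (any(has_bad)) {
    first <- which(has_bad)[1]
    msg <- sprintf("record '%s' contains non-standard residue '%s'",
                   records$id[first], bad_chr[1])
    if (on_invalid == "error") stop(msg)
    if (on_invalid == "skip") {
      warning(msg, "; dropping ", sum(has_bad), " record(s)")
      records <- records[!has_bad, , drop = FALSE]
    } else {
      warning(msg, "; stripping non-standard residues from ",
              sum(has_bad), " record(s)")
      records$sequence <- gsub(pattern, "", records$sequence)
    }
  }
  if (any(nchar(records$sequence) == 0)) stop("record with empty sequence")
  if (anyDuplicated(records$id)) {
    stop("duplicate record id(s): ",
         paste(unique(records$id[duplicated(records$id)]), collapse = ", "))
  }
  rownames(records) <- NULL
  records
}

#' Write protein records as FASTA
#'
#' @param records A `data.frame` with columns `id`, `description`, `sequence`.
#' @param path Output file path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  stopifnot(is.data.frame(records), width >= 1)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    header <- if (nzchar(records$description[i] %||% "")) {
      paste0(">", records$id[i], " ", records$description[i])
    } else {
      paste0(">", records$id[i])
    }
    writeLines(header, con)
    s <- records$sequence[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Write and read tabular results as CSV
#'
#' RFC-4180-style CSV with a header line; rows are written in input order so
#' repeat runs are byte-identical.
#'
#' @param rows A `data.frame` of result rows (may have zero rows).
#' @param path File path.
#' @return `write_results_csv()` returns `path` invisibly;
#'   `read_results_csv()` returns a `data.frame`.
#' @export
write_results_csv <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  utils::write.csv(rows, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_results_csv
#' @export
read_results_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
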