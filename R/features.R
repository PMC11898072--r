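# The 20-feature physicochemical descriptor of a peptide: residue-class
# frequencies, scale averages, Henderson-Hasselbalch charge, isoelectric
# point and the dipeptide instability index.

#' Canonical feature order
#'
#' The frozen, alphabetical order of the twenty descriptor values. Trained
#' models store and check this order; any mismatch between a model bundle
#' and a feature matrix is a hard error.
#'
#' @return Character vector of length 20.
#' @export
feature_names <- function() {
  c("charge_at_pH7.4", "freq_acidic", "freq_all_basic",
    "freq_all_helix_breaker", "freq_aromatic", "freq_basic", "freq_hbond",
    "freq_hydroxyl", "freq_nonpolar", "freq_ring",
    "freq_strong_helix_breaker", "helix_propensity", "hydrophobicity_index",
    "hydropathy_index", "instability_index", "isoelectric_point",
    "rna_ligation", "redox_potential", "sheet_propensity", "turn_propensity")
}

#' @noRd
.seq_chars <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (nchar(sequence) == 0) stop("empty sequence")
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, amino_acids())
  if (length(bad) > 0) {
    stop("non-standard residue(s): ", paste(unique(bad), collapse = ", "))
  }
  chars
}

#' Fraction of residues belonging to a class
#'
#' @param sequence Peptide string.
#' @param cls Character vector of one-letter codes defining the class.
#' @return Count of residues in `cls` divided by peptide length, in `[0, 1]`.
#' @export
#' @examples
#' class_frequency("KKKK", c("K", "R"))  # 1
class_frequency <- function(sequence, cls) {
  chars <- .seq_chars(sequence)
  sum(chars %in% cls) / length(chars)
}

#' Mean per-residue scale value
#'
#' @param sequence Peptide string.
#' @param scale Named numeric vector mapping residues to values; must cover
#'   every residue present.
#' @return Arithmetic mean of the per-residue values.
#' @export
scale_average <- function(sequence, scale) {
  chars <- .seq_chars(sequence)
  missing <- setdiff(chars, names(scale))
  if (length(missing) > 0) {
    stop("scale does not define residue(s): ", paste(missing, collapse = ", "))
  }
  mean(scale[chars])
}

# Net charge from residue counts (internal; avoids re-splitting the string
# during pI bisection).
.charge_from_counts <- function(counts, pH, pka, include_termini) {
  basic_groups <- c("K", "R", "H")
  acidic_groups <- c("C", "D", "E", "Y")
  pos <- sum(vapply(basic_groups, function(a) {
    n <- counts[[a]] %||% 0
    if (n == 0) 0 else n / (1 + 10^(pH - pka$sidechain[[a]]))
  }, 0))
  neg <- sum(vapply(acidic_groups, function(a) {
    n <- counts[[a]] %||% 0
    if (n == 0) 0 else n / (1 + 10^(pka$sidechain[[a]] - pH))
  }, 0))
  if (include_termini) {
    pos <- pos + 1 / (1 + 10^(pH - pka$nterm))
    neg <- neg + 1 / (1 + 10^(pka$cterm - pH))
  }
  pos - neg
}

#' Henderson-Hasselbalch net charge at a given pH
#'
#' Sums, over basic groups (K, R, H side chains, optionally the amino
#' terminus), the protonated fraction `1 / (1 + 10^(pH - pKa))`, and
#' subtracts over acidic groups (D, E, C, Y side chains, optionally the
#' carboxy terminus) the dissociated fraction `1 / (1 + 10^(pKa - pH))`.
#' Termini are excluded by default because scored segments are internal
#' stretches of a longer chain.
#'
#' @param sequence Peptide string.
#' @param pH pH value in `[0, 14]`.
#' @param config A [scale_config()] providing the pKa table.
#' @param include_termini Include the free termini as ionizable groups?
#' @return Net charge (signed real).
#' @export
#' @examples
#' charge_at_ph("AAAA")            # 0: no ionizable side chains
#' charge_at_ph("D", pH = 3.9)     # -0.5: half-dissociation at its pKa
charge_at_ph <- function(sequence, pH = 7.4, config = scale_config(),
                         include_termini = FALSE) {
  stopifnot(pH >= 0, pH <= 14)
  chars <- .seq_chars(sequence)
  counts <- as.list(table(chars))
  .charge_from_counts(counts, pH, config$pka, include_termini)
}

#' Isoelectric point by bisection
#'
#' The pH in `[0, 14]` at which [charge_at_ph()] crosses zero, located by
#' bisection to a tolerance of 1e-4 pH units (net charge is monotonically
#' non-increasing in pH, so the zero is unique when it exists). Conventions
#' for degenerate peptides: with no ionizable groups at all the pI is
#' reported as 7.0; when the charge keeps one sign over the whole range
#' (only basic or only acidic groups, termini excluded) the endpoint of
#' minimal absolute charge (14 or 0) is returned.
#'
#' @inheritParams charge_at_ph
#' @param tol Bisection tolerance in pH units.
#' @return pI in `[0, 14]`.
#' @export
#' @examples
#' isoelectric_point("AAAA")  # 7: no ionizable groups
isoelectric_point <- function(sequence, config = scale_config(),
                              include_termini = FALSE, tol = 1e-4) {
  chars <- .seq_chars(sequence)
  counts <- as.list(table(chars))
  ionizable <- c("K", "R", "H", "C", "D", "E", "Y")
  if (!include_termini && !any(ionizable %in% names(counts))) return(7.0)
  f <- function(pH) .charge_from_counts(counts, pH, config$pka, include_termini)
  lo <- 0; hi <- 14
  flo <- f(lo); fhi <- f(hi)
  if (flo <= 0) return(0)
  if (fhi >= 0) return(14)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Dipeptide-based instability index
#'
#' `(10 / L) * sum(DIWV[x_i, x_{i+1}])` over the `L - 1` adjacent residue
#' pairs, with the Guruprasad dipeptide instability weights from the scale
#' configuration.
#'
#' @param sequence Peptide string of length >= 2.
#' @param config A [scale_config()] providing the `diwv` matrix.
#' @return The instability index (values above ~40 flag unstable peptides).
#' @export
instability_index <- function(sequence, config = scale_config()) {
  chars <- .seq_chars(sequence)
  L <- length(chars)
  if (L < 2) stop("instability index needs at least 2 residues")
  w <- config$diwv[cbind(chars[-L], chars[-1])]
  (10 / L) * sum(w)
}

#' Compute the 20-feature descriptor of a peptide
#'
#' Assembles, in the canonical [feature_names()] order: net charge at pH
#' 7.4, ten residue-class frequencies, five conformational/hydrophobicity
#' scale averages, the instability index, the isoelectric point, and the
#' RNA-ligation and redox scale averages. A pure function of the sequence
#' and configuration.
#'
#' @param sequence Peptide string of length >= 2, standard residues only.
#' @param config A [scale_config()].
#' @return Named numeric vector of length 20 in canonical order.
#' @export
#' @examples
#' compute_features("MKKLLEEAQRH")[c("freq_basic", "isoelectric_point")]
compute_features <- function(sequence, config = scale_config()) {
  chars <- .seq_chars(sequence)
  if (length(chars) < 2) stop("need at least 2 residues to featurize")
  L <- length(chars)
  cls <- config$classes
  freq <- function(set) sum(chars %in% set) / L
  savg <- function(nm) mean(config$scales[[nm]][chars])
  counts <- as.list(table(chars))
  vals <- c(
    "charge_at_pH7.4" = .charge_from_counts(counts, 7.4, config$pka, FALSE),
    freq_acidic = freq(cls$acidic),
    freq_all_basic = freq(cls$all_basic),
    freq_all_helix_breaker = freq(cls$helix_breaker),
    freq_aromatic = freq(cls$aromatic),
    freq_basic = freq(cls$basic),
    freq_hbond = freq(cls$hbond),
    freq_hydroxyl = freq(cls$hydroxyl),
    freq_nonpolar = freq(cls$nonpolar),
    freq_ring = freq(cls$ring),
    freq_strong_helix_breaker = freq(cls$strong_helix_breaker),
    helix_propensity = savg("helix_propensity"),
    hydrophobicity_index = savg("hydrophobicity"),
    hydropathy_index = savg("hydropathy"),
    instability_index = instability_index(sequence, config),
    isoelectric_point = isoelectric_point(sequence, config),
    rna_ligation = savg("rna_ligation"),
    redox_potential = savg("redox"),
    sheet_propensity = savg("sheet_propensity"),
    turn_propensity = savg("turn_propensity")
  )
  names(vals) <- feature_names()
  vals
}

#' Feature matrix for many peptides
#'
#' @param sequences Character vector of peptides.
#' @param config A [scale_config()].
#' @return Numeric matrix, one row per peptide, 20 columns in canonical
#'   order.
#' @export
compute_feature_matrix <- function(sequences, config = scale_config()) {
  m <- t(vapply(sequences, compute_features,
                numeric(20), config = config, USE.NAMES = FALSE))
  colnames(m) <- feature_names()
  m
}
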