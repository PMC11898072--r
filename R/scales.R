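# Per-residue constants behind the 20-feature descriptor: residue class
# sets, propensity and hydrophobicity scales, side-chain pKa values and the
# dipeptide instability weight table. All of them live in a ScaleConfig list
# so every table can be overridden without touching code.

#' The twenty standard amino acids
#'
#' One-letter codes, alphabetical. Every scale in a [scale_config()] is
#' defined over exactly this alphabet.
#'
#' @return Character vector of length 20.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

.aa_vec <- function(...) {
  v <- c(...)
  stopifnot(length(v) == 20)
  names(v) <- amino_acids()
  v
}

# Chou-Fasman conformational propensities.
.HELIX_PROPENSITY <- .aa_vec(
  1.42, 0.70, 1.01, 1.51, 1.13, 0.57, 1.00, 1.08, 1.16, 1.21,
  1.45, 0.67, 0.57, 1.11, 0.98, 0.77, 0.83, 1.06, 1.08, 0.69)
.SHEET_PROPENSITY <- .aa_vec(
  0.83, 1.19, 0.54, 0.37, 1.38, 0.75, 0.87, 1.60, 0.74, 1.30,
  1.05, 0.89, 0.55, 1.10, 0.93, 0.75, 1.19, 1.70, 1.37, 1.47)
.TURN_PROPENSITY <- .aa_vec(
  0.66, 1.19, 1.46, 0.74, 0.60, 1.56, 0.95, 0.47, 1.01, 0.59,
  0.60, 1.56, 1.52, 0.98, 0.95, 1.43, 0.96, 0.50, 0.96, 1.14)

# Kyte-Doolittle hydropathy.
.HYDROPATHY <- .aa_vec(
  1.8, 2.5, -3.5, -3.5, 2.8, -0.4, -3.2, 4.5, -3.9, 3.8,
  1.9, -3.5, -1.6, -3.5, -4.5, -0.8, -0.7, 4.2, -0.9, -1.3)

# Eisenberg consensus hydrophobicity.
.HYDROPHOBICITY <- .aa_vec(
  0.62, 0.29, -0.90, -0.74, 1.19, 0.48, -0.40, 1.38, -1.50, 1.06,
  0.64, -0.78, 0.12, -0.85, -2.53, -0.18, -0.05, 1.08, 0.81, 0.26)

# RNA-interface enrichment style scale: arginine, lysine, histidine and
# methionine are over-represented at protein-RNA interfaces, aspartate and
# glutamate depleted. A documented substitute scale (see vignette).
.RNA_LIGATION <- .aa_vec(
  0.00, 0.10, -0.60, -0.60, 0.20, 0.20, 0.60, 0.00, 0.80, 0.00,
  0.40, 0.20, 0.00, 0.10, 1.00, 0.10, 0.10, 0.00, 0.20, 0.30)

# Redox propensity: non-zero only for the redox-active side chains
# (C, M, W, Y, H). A documented substitute scale (see vignette).
.REDOX <- .aa_vec(
  0.0, 0.8, 0.0, 0.0, 0.0, 0.0, 0.3, 0.0, 0.0, 0.0,
  0.5, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.4, 0.4)

# Guruprasad dipeptide instability weights, DIWV[first, second].
.DIWV <- matrix(c(
  1, 44.94, -7.49, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 1,
  1, 1, 20.26, 1, 1, 1, 33.6, 1, 1, 20.26, 33.6, 1, 20.26, -6.54, 1, 1, 33.6, -6.54, 24.68, 1,
  1, 1, 1, 1, -6.54, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, -6.54, 20.26, -14.03, 1, 1, 1,
  1, 44.94, 20.26, 33.6, 1, 1, -6.54, 20.26, 1, 1, 1, 1, 20.26, 20.26, 1, 20.26, 1, 1, -14.03, 1,
  1, 1, 13.34, 1, 1, 1, 1, 1, -14.03, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 33.601,
  -7.49, 1, 1, -6.54, 1, 13.34, 1, -7.49, -7.49, 1, 1, -7.49, 1, 1, 1, 1, -7.49, 1, 13.34, -7.49,
  1, 1, 1, 1, -9.37, -9.37, 1, 44.94, 24.68, 1, 1, 24.68, -1.88, 1, 1, 1, -6.54, 1, -1.88, 44.94,
  1, 1, 1, 44.94, 1, 1, 13.34, 1, -7.49, 20.26, 1, 1, -1.88, 1, 1, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, -7.49, 1, -7.49, 1, -7.49, 33.6, 1, -6.54, 24.64, 33.6, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, 1, 1, 1, -7.49, 1, 1, 1, 20.26, 33.6, 20.26, 1, 1, 1, 24.68, 1,
  13.34, 1, 1, 1, 1, 1, 58.28, 1, 1, 1, -1.88, 1, 44.94, -6.54, -6.54, 44.94, -1.88, 1, 1, 24.68,
  1, -1.88, 1, 1, -14.03, -14.03, 1, 44.94, 24.68, 1, 1, 1, -1.88, -6.54, 1, 1, -7.49, 1, -9.37, 1,
  20.26, -6.54, -6.54, 18.38, 20.26, 1, 1, 1, 1, 1, -6.54, 1, 20.26, 20.26, -6.54, 20.26, 1, 20.26, -1.88, 1,
  1, -6.54, 20.26, 20.26, -6.54, 1, 1, 1, 1, 1, 1, 1, 20.26, 20.26, 1, 44.94, 1, -6.54, 1, -6.54,
  1, 1, 1, 1, 1, -7.49, 20.26, 1, 1, 1, 1, 13.34, 20.26, 20.26, 58.28, 44.94, 1, 1, 58.28, -6.54,
  1, 33.6, 1, 20.26, 1, 1, 1, 1, 1, 1, 1, 1, 44.94, 20.26, 20.26, 20.26, 1, 1, 1, 1,
  1, 1, 1, 20.26, 13.34, -7.49, 1, 1, 1, 1, 1, -14.03, 1, -6.54, 1, 1, 1, 1, -14.03, 1,
  1, 1, -14.03, 1, 1, -7.49, 1, 1, -1.88, 1, 1, 1, 20.26, 1, 1, 1, -7.49, 1, 1, -6.54,
  -14.03, 1, 1, 1, 1, -9.37, 24.68, 1, 1, 13.34, 24.68, 13.34, 1, 1, 1, 1, -14.03, -7.49, 1, 1,
  24.68, 1, 24.68, -6.54, 1, -7.49, 13.34, 1, 1, 1, 44.94, 1, 13.34, 1, -15.91, 1, -7.49, 1, -9.37, 13.34
), nrow = 20, byrow = TRUE,
  dimnames = list(amino_acids(), amino_acids()))

#' Default scale configuration
#'
#' Bundles every per-residue constant used by [compute_features()]: residue
#' class sets, conformational propensity scales (Chou-Fasman), hydropathy
#' (Kyte-Doolittle) and hydrophobicity (Eisenberg consensus) scales, RNA
#' ligation and redox substitute scales, EMBOSS-style pKa values and the
#' Guruprasad dipeptide instability weights. Each table can be replaced to
#' re-define a feature without code changes; [write_scale_config()] /
#' [read_scale_config()] round-trip the whole object through a YAML file.
#'
#' @return A list of class `scale_config` with elements `classes` (named
#'   list of residue sets), `scales` (named list of per-residue numeric
#'   vectors), `pka` (named list: side-chain pKa values plus `nterm`,
#'   `cterm`) and `diwv` (20 x 20 dipeptide weight matrix).
#' @export
#' @examples
#' cfg <- scale_config()
#' names(cfg$classes)
scale_config <- function() {
  cfg <- list(
    classes = list(
      acidic               = c("D", "E"),
      basic                = c("K", "R"),
      all_basic            = c("K", "R", "H"),
      aromatic             = c("F", "W", "Y"),
      ring                 = c("F", "W", "Y", "H", "P"),
      hydroxyl             = c("S", "T", "Y"),
      hbond                = c("S", "T", "Y", "N", "Q", "D", "E", "K", "R", "H", "W"),
      nonpolar             = c("A", "V", "L", "I", "M", "F", "W", "P", "G"),
      helix_breaker        = c("P", "G"),
      strong_helix_breaker = "P"
    ),
    scales = list(
      helix_propensity = .HELIX_PROPENSITY,
      sheet_propensity = .SHEET_PROPENSITY,
      turn_propensity  = .TURN_PROPENSITY,
      hydropathy       = .HYDROPATHY,
      hydrophobicity   = .HYDROPHOBICITY,
      rna_ligation     = .RNA_LIGATION,
      redox            = .REDOX
    ),
    pka = list(
      sidechain = c(C = 8.5, D = 3.9, E = 4.1, H = 6.5, K = 10.5, R = 12.5, Y = 10.1),
      nterm = 8.6,
      cterm = 3.6
    ),
    diwv = .DIWV
  )
  class(cfg) <- "scale_config"
  cfg
}

#' @noRd
validate_scale_config <- function(config) {
  stopifnot(inherits(config, "scale_config") || is.list(config))
  aas <- amino_acids()
  for (nm in names(config$classes)) {
    bad <- setdiff(config$classes[[nm]], aas)
    if (length(bad) > 0) {
      stop("class set '", nm, "' contains non-standard residues: ",
           paste(bad, collapse = ", "))
    }
  }
  for (nm in names(config$scales)) {
    if (!all(aas %in% names(config$scales[[nm]]))) {
      stop("scale '", nm, "' does not define all 20 residues")
    }
  }
  stopifnot(identical(dim(config$diwv), c(20L, 20L)))
  invisible(config)
}

#' Fingerprint a scale configuration
#'
#' Short hex digest of every numeric table in the configuration; stored in
#' model-bundle manifests so a bundle trained under one set of scales
#' refuses to score features computed under another.
#'
#' @param config A [scale_config()] object.
#' @return A character scalar (8 hex digits).
#' @export
scale_config_hash <- function(config = scale_config()) {
  validate_scale_config(config)
  parts <- c(
    vapply(config$classes, function(s) paste(sort(s), collapse = ""), ""),
    vapply(config$scales, function(s) paste(sprintf("%.6g", s[amino_acids()]), collapse = ","), ""),
    paste(sprintf("%.6g", unlist(config$pka)), collapse = ","),
    paste(sprintf("%.6g", as.vector(config$diwv)), collapse = ",")
  )
  djb2_hash(parts)
}

#' Write or read a scale configuration as YAML
#'
#' Human-editable serialisation of a [scale_config()]. The DIWV matrix is
#' stored row-wise under its residue labels.
#'
#' @param config A `scale_config` object.
#' @param path File path.
#' @return `write_scale_config()` returns `path` invisibly;
#'   `read_scale_config()` returns a `scale_config` object.
#' @export
write_scale_config <- function(config, path) {
  validate_scale_config(config)
  out <- list(
    classes = lapply(config$classes, as.character),
    scales  = lapply(config$scales, function(s) as.list(s[amino_acids()])),
    pka     = list(sidechain = as.list(config$pka$sidechain),
                   nterm = config$pka$nterm, cterm = config$pka$cterm),
    diwv    = stats::setNames(
      lapply(seq_len(20), function(i) as.list(stats::setNames(config$diwv[i, ], amino_acids()))),
      amino_acids())
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_scale_config
#' @export
read_scale_config <- function(path) {
  raw <- yaml::read_yaml(path)
  aas <- amino_acids()
  cfg <- list(
    classes = lapply(raw$classes, as.character),
    scales  = lapply(raw$scales, function(s) unlist(s)[aas]),
    pka     = list(sidechain = unlist(raw$pka$sidechain),
                   nterm = raw$pka$nterm, cterm = raw$pka$cterm),
    diwv    = do.call(rbind, lapply(aas, function(a) unlist(raw$diwv[[a]])[aas]))
  )
  rownames(cfg$diwv) <- aas
  class(cfg) <- "scale_config"
  validate_scale_config(cfg)
  cfg
}
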