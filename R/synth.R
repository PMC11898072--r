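# Seeded generator of training fixtures and toy proteomes. Positives mimic
# the basic-residue-enriched, R3H-motif-bearing KhpB carboxy-terminal helix
# 22-mers; negatives mimic albumin helices (helix-forming but basic-poor)
# plus uniform-random 22-mers; class sizes follow the published training
# design (2560 / 701 / 1859, 70/30 split downstream).

# Residue sampling distributions. Positive peptides put 0.35 of the mass on
# {K,R,H} and 0.45 on the helix formers {A,E,L,M,Q}; albumin-like negatives
# keep the helix-former mass but deplete basics to 0.05; the toy-proteome
# background is helix-poor so planted helices dominate detection.
.COMP_POSITIVE <- c(
  A = 0.120, C = 0.010, D = 0.020, E = 0.110, F = 0.015, G = 0.020,
  H = 0.060, I = 0.020, K = 0.150, L = 0.120, M = 0.040, N = 0.020,
  P = 0.010, Q = 0.060, R = 0.140, S = 0.025, T = 0.025, V = 0.020,
  W = 0.005, Y = 0.010)
.COMP_ALBUMIN <- c(
  A = 0.160, C = 0.020, D = 0.050, E = 0.140, F = 0.040, G = 0.030,
  H = 0.005, I = 0.030, K = 0.030, L = 0.150, M = 0.050, N = 0.030,
  P = 0.020, Q = 0.080, R = 0.015, S = 0.040, T = 0.040, V = 0.040,
  W = 0.010, Y = 0.020)
.COMP_HELIX_POOR <- c(
  A = 0.015, C = 0.030, D = 0.090, E = 0.015, F = 0.050, G = 0.130,
  H = 0.005, I = 0.060, K = 0.010, L = 0.015, M = 0.005, N = 0.080,
  P = 0.090, Q = 0.010, R = 0.005, S = 0.120, T = 0.120, V = 0.080,
  W = 0.020, Y = 0.050)

#' Synthetic training-set specification
#'
#' Defines the synthetic stand-in for the published training design: `n_pos`
#' basic-enriched R3H-motif helical 22-mers as positives, `n_neg_albumin`
#' albumin-like helical 22-mers plus `n_neg_random` uniform-random 22-mers
#' as negatives. Defaults reproduce the published class sizes.
#'
#' @param n_pos Number of positive peptides.
#' @param n_neg_albumin Number of albumin-like negative peptides.
#' @param n_neg_random Number of uniform-random negative peptides.
#' @param length Peptide length (residues).
#' @param seed Integer seed; all generation is deterministic given it.
#' @param pos_basic_enrichment Probability mass placed on {K, R, H} in
#'   positive peptides.
#' @param embed_r3h Plant an RxxxH motif (R and H four positions apart) in
#'   each positive peptide?
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_pos = 2560, n_neg_albumin = 701,
                           n_neg_random = 1859, length = 22, seed = 0,
                           pos_basic_enrichment = 0.35, embed_r3h = TRUE) {
  stopifnot(n_pos >= 0, n_neg_albumin >= 0, n_neg_random >= 0, length >= 6,
            pos_basic_enrichment > 0, pos_basic_enrichment < 1)
  structure(list(n_pos = as.integer(n_pos),
                 n_neg_albumin = as.integer(n_neg_albumin),
                 n_neg_random = as.integer(n_neg_random),
                 length = as.integer(length), seed = as.integer(seed),
                 pos_basic_enrichment = pos_basic_enrichment,
                 embed_r3h = isTRUE(embed_r3h)),
            class = "synthetic_spec")
}

# Rescale the positive composition so {K,R,H} carry `enrichment` mass.
#' @noRd
.positive_composition <- function(enrichment) {
  comp <- .COMP_POSITIVE
  basics <- c("K", "R", "H")
  comp[basics] <- comp[basics] * enrichment / sum(comp[basics])
  others <- setdiff(names(comp), basics)
  comp[others] <- comp[others] * (1 - enrichment) / sum(comp[others])
  comp
}

#' @noRd
.sample_peptides <- function(n, length, comp) {
  vapply(seq_len(n), function(i) {
    paste(sample(names(comp), length, replace = TRUE, prob = comp),
          collapse = "")
  }, "")
}

#' Generate synthetic positive peptides
#'
#' Basic-residue-enriched, helix-former-rich peptides of fixed length; when
#' `spec$embed_r3h` is set, each carries an R3H motif (R at a random
#' admissible position `i`, H at `i + 4`). Byte-identical output for equal
#' seeds.
#'
#' @param spec A [synthetic_spec()].
#' @return A record `data.frame` (`id`, `description`, `sequence`).
#' @export
generate_positive <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$length < 6) stop("peptide length must be >= 6")
  comp <- .positive_composition(spec$pos_basic_enrichment)
  with_rseed(derive_seed(spec$seed, "synth", "positive"), {
    seqs <- .sample_peptides(spec$n_pos, spec$length, comp)
    if (spec$embed_r3h && spec$n_pos > 0) {
      pos <- sample.int(spec$length - 4L, spec$n_pos, replace = TRUE)
      seqs <- vapply(seq_along(seqs), function(i) {
        chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
        chars[pos[i]] <- "R"
        chars[pos[i] + 4L] <- "H"
        paste(chars, collapse = "")
      }, "")
    }
    data.frame(
      id = sprintf("pos_%05d", seq_len(spec$n_pos)),
      description = rep("synthetic KhpB-like R3H helix (positive)", spec$n_pos),
      sequence = seqs, stringsAsFactors = FALSE)
  })
}

#' Generate synthetic negative peptides
#'
#' Two subclasses, labelled in the `description` column: albumin-like
#' peptides (helix-former-rich but basic-depleted) and uniform-random
#' peptides over the 20-letter alphabet.
#'
#' @param spec A [synthetic_spec()].
#' @return A record `data.frame` (`id`, `description`, `sequence`).
#' @export
generate_negative <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$length < 6) stop("peptide length must be >= 6")
  with_rseed(derive_seed(spec$seed, "synth", "negative"), {
    alb <- .sample_peptides(spec$n_neg_albumin, spec$length, .COMP_ALBUMIN)
    uni_comp <- stats::setNames(rep(0.05, 20), amino_acids())
    rnd <- .sample_peptides(spec$n_neg_random, spec$length, uni_comp)
    data.frame(
      id = c(sprintf("neg_alb_%05d", seq_len(spec$n_neg_albumin)),
             sprintf("neg_rnd_%05d", seq_len(spec$n_neg_random))),
      description = c(rep("synthetic albumin-like helix (negative)",
                          spec$n_neg_albumin),
                      rep("random peptide (negative)", spec$n_neg_random)),
      sequence = c(alb, rnd), stringsAsFactors = FALSE)
  })
}

#' Build the labelled synthetic training set
#'
#' Generates positives and negatives under `spec`, featurizes every peptide
#' and returns the labelled dataset consumed by the training functions.
#'
#' @param spec A [synthetic_spec()].
#' @param config A [scale_config()].
#' @return A [labelled_dataset()].
#' @export
generate_training_set <- function(spec = synthetic_spec(),
                                  config = scale_config()) {
  pos <- generate_positive(spec)
  neg <- generate_negative(spec)
  recs <- rbind(pos, neg)
  x <- compute_feature_matrix(recs$sequence, config)
  labelled_dataset(x, c(rep(TRUE, nrow(pos)), rep(FALSE, nrow(neg))),
                   ids = recs$id)
}

#' Load a labelled training set from FASTA files
#'
#' Drop-in replacement for [generate_training_set()] when real labelled
#' helix peptides are available as two FASTA files.
#'
#' @param positive_fasta,negative_fasta FASTA paths for the two classes.
#' @param config A [scale_config()].
#' @return A [labelled_dataset()].
#' @export
load_training_set <- function(positive_fasta, negative_fasta,
                              config = scale_config()) {
  pos <- read_fasta(positive_fasta)
  neg <- read_fasta(negative_fasta)
  x <- compute_feature_matrix(c(pos$sequence, neg$sequence), config)
  labelled_dataset(x, c(rep(TRUE, nrow(pos)), rep(FALSE, nrow(neg))),
                   ids = c(paste0("pos|", pos$id), paste0("neg|", neg$id)))
}

.NABP_DESCRIPTIONS <- c(
  "DNA polymerase III subunit alpha",
  "ATP-dependent RNA helicase DeaD",
  "ribosomal protein L7/L12",
  "histone-like DNA-binding protein HU",
  "RNA-binding protein Hfq",
  "transcription factor sigma-54",
  "ribonuclease E; RNase E family endonuclease",
  "chromatin remodelling ATPase",
  "argonaute-family protein",
  "snRNP Sm-like core protein")

.OTHER_DESCRIPTIONS <- c(
  "membrane transporter",
  "ABC transporter permease subunit",
  "outer membrane lipoprotein",
  "enolase-like glycolytic enzyme",
  "cell wall hydrolase",
  "flagellar motor stator protein",
  "two-component sensor kinase",
  "lipid A biosynthesis acyltransferase")

#' Generate a toy proteome with planted nucleic-acid-binding proteins
#'
#' Builds `n_nabp` proteins that each contain at least one planted
#' positive-like helical 22-mer and carry a functional annotation drawn
#' from the nucleic-acid-binding keyword vocabulary, plus `n_other`
#' helix-poor proteins with neutral annotations. A stand-in benchmark for
#' whole-proteome recovery runs.
#'
#' @param n_nabp Number of planted nucleic-acid-binding proteins.
#' @param n_other Number of background proteins.
#' @param seed Integer seed.
#' @param min_length,max_length Protein length range (before insertion).
#' @return A list with elements `records` (id, description, sequence),
#'   `annotations` (id, description) and `nabp_ids`.
#' @export
generate_toy_proteome <- function(n_nabp = 10, n_other = 90, seed = 0,
                                  min_length = 80, max_length = 200) {
  stopifnot(n_nabp >= 0, n_other >= 0, min_length >= 30,
            max_length >= min_length)
  comp_pos <- .positive_composition(0.35)
  with_rseed(derive_seed(seed, "synth", "proteome"), {
    make_background <- function() {
      len <- sample(min_length:max_length, 1)
      paste(sample(names(.COMP_HELIX_POOR), len, replace = TRUE,
                   prob = .COMP_HELIX_POOR), collapse = "")
    }
    nabp <- lapply(seq_len(n_nabp), function(i) {
      bg <- make_background()
      # redraw until the insert itself contains a qualifying helix window,
      # so every planted protein is guaranteed one detectable segment
      repeat {
        insert <- paste(sample(names(comp_pos), 22, replace = TRUE,
                               prob = comp_pos), collapse = "")
        ins_chars <- strsplit(insert, "", fixed = TRUE)[[1]]
        p <- sample.int(18L, 1)
        ins_chars[p] <- "R"; ins_chars[p + 4L] <- "H"
        insert <- paste(ins_chars, collapse = "")
        if (nrow(extract_helices(insert, id = "probe")) > 0) break
      }
      at <- sample.int(nchar(bg) - 1L, 1)
      list(id = sprintf("nabp_%03d", i),
           description = sample(.NABP_DESCRIPTIONS, 1),
           sequence = paste0(substring(bg, 1, at), insert,
                             substring(bg, at + 1, nchar(bg))))
    })
    other <- lapply(seq_len(n_other), function(i) {
      list(id = sprintf("prot_%03d", i),
           description = sample(.OTHER_DESCRIPTIONS, 1),
           sequence = make_background())
    })
    all <- c(nabp, other)
    records <- data.frame(
      id = vapply(all, `[[`, "", "id"),
      description = vapply(all, `[[`, "", "description"),
      sequence = vapply(all, `[[`, "", "sequence"),
      stringsAsFactors = FALSE)
    list(records = records,
         annotations = records[, c("id", "description")],
         nabp_ids = records$id[seq_len(n_nabp)])
  })
}

#' Write toy-proteome annotations as TSV
#'
#' @param annotations A `data.frame` with columns `id`, `description`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations[, c("id", "description")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV annotation table
#'
#' @param path Path to a tab-separated file with columns `id`, `description`.
#' @return A `data.frame`.
#' @export
read_annotations <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
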