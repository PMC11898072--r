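# Model-bundle persistence: one serialized member per file plus a
# plain-text manifest (member order, feature order, seed, scales hash) so a
# bundle can be audited and a feature-order or scale mismatch is caught at
# load/predict time rather than producing silently misaligned scores.

#' Save a trained ensemble as a model bundle
#'
#' Writes one serialized model per member (`member_<i>_<family>.rds`) and a
#' human-readable `manifest.txt` holding the member order, the canonical
#' feature order, the training seed and the scale-configuration hash.
#'
#' @param ensemble A trained `nabh_ensemble`.
#' @param dir Bundle directory (created if missing).
#' @param config The [scale_config()] the training features were computed
#'   under; its hash is recorded for verification.
#' @return `dir`, invisibly.
#' @export
save_bundle <- function(ensemble, dir, config = scale_config()) {
  stopifnot(inherits(ensemble, "nabh_ensemble"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fams <- names(ensemble$members)
  files <- sprintf("member_%d_%s.rds", seq_along(fams), fams)
  for (i in seq_along(fams)) {
    saveRDS(ensemble$members[[i]], file.path(dir, files[i]))
  }
  manifest <- c(
    paste0("package: nabhelix"),
    paste0("version: ", as.character(utils::packageVersion("nabhelix"))),
    paste0("n_members: ", length(fams)),
    paste0("members: ", paste(fams, collapse = ",")),
    paste0("member_files: ", paste(files, collapse = ",")),
    paste0("feature_order: ", paste(ensemble$feature_order, collapse = ",")),
    paste0("seed: ", ensemble$seed),
    paste0("scales_hash: ", scale_config_hash(config))
  )
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' @noRd
read_manifest <- function(dir) {
  path <- file.path(dir, "manifest.txt")
  if (!file.exists(path)) stop("no manifest.txt in bundle directory: ", dir)
  lines <- readLines(path)
  keys <- sub(":.*$", "", lines)
  vals <- sub("^[^:]+:\\s*", "", lines)
  stats::setNames(as.list(vals), keys)
}

#' Load a model bundle
#'
#' Reads the manifest, verifies that the recorded feature order matches the
#' package's canonical [feature_names()] order and that the scales hash
#' matches `config`, then deserializes the members. Any mismatch is a hard
#' error.
#'
#' @param dir Bundle directory written by [save_bundle()].
#' @param config The [scale_config()] in force; must hash to the manifest's
#'   `scales_hash`.
#' @return A `nabh_ensemble`.
#' @export
load_bundle <- function(dir, config = scale_config()) {
  man <- read_manifest(dir)
  feats <- strsplit(man$feature_order, ",", fixed = TRUE)[[1]]
  if (!identical(feats, feature_names())) {
    stop("bundle feature order does not match this package's canonical ",
         "feature order; refusing to score misaligned features")
  }
  if (!identical(man$scales_hash, scale_config_hash(config))) {
    stop("bundle was trained under a different scale configuration ",
         "(hash ", man$scales_hash, " != ", scale_config_hash(config), ")")
  }
  fams <- strsplit(man$members, ",", fixed = TRUE)[[1]]
  files <- strsplit(man$member_files, ",", fixed = TRUE)[[1]]
  members <- lapply(file.path(dir, files), readRDS)
  names(members) <- fams
  structure(list(members = members, feature_order = feats,
                 seed = as.integer(man$seed),
                 metadata = list(n_members = length(members))),
            class = "nabh_ensemble")
}
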