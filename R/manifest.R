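manifest_cols <- c("study", "protein_id", "intermediate_index",
                   "conformation_label", "pdb_id",
                   "deposited_start", "deposited_end",
                   "modeled_start", "modeled_end",
                   "is_native", "excluded", "exclusion_reason")

#' Read a conformation manifest
#'
#' The manifest is a TSV catalogue of folding-intermediate conformations: one
#' row per deposited conformation with its study, protein, time index,
#' conformation label, PDB id, deposited and modeled sequence ranges, native
#' flag and (optional) exclusion flag plus reason. Ranges may be supplied
#' either as `deposited_start`/`deposited_end` (and `modeled_*`) integer
#' columns, or as single `deposited_range`/`modeled_range` text columns such
#' as `"1-27"` (en-dashes are normalized).
#'
#' @param path TSV file path.
#' @return A validated manifest tibble.
#' @export
read_manifest <- function(path) {
  m <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  parse_range <- function(txt, what) {
    txt <- gsub("–|—", "-", txt)
    parts <- strsplit(txt, "-", fixed = TRUE)
    bad <- vapply(parts, function(p) length(p) != 2L ||
                    anyNA(suppressWarnings(as.integer(p))), logical(1))
    if (any(bad)) {
      rlang::abort(sprintf("unparseable %s value(s): %s", what,
                           paste(unique(txt[bad]), collapse = ", ")))
    }
    list(start = vapply(parts, function(p) as.integer(p[1]), integer(1)),
         end = vapply(parts, function(p) as.integer(p[2]), integer(1)))
  }
  if ("deposited_range" %in% names(m) && !"deposited_start" %in% names(m)) {
    r <- parse_range(m$deposited_range, "deposited_range")
    m$deposited_start <- r$start
    m$deposited_end <- r$end
    m$deposited_range <- NULL
  }
  if ("modeled_range" %in% names(m) && !"modeled_start" %in% names(m)) {
    r <- parse_range(m$modeled_range, "modeled_range")
    m$modeled_start <- r$start
    m$modeled_end <- r$end
    m$modeled_range <- NULL
  }
  missing <- setdiff(setdiff(manifest_cols, "exclusion_reason"), names(m))
  if (length(missing) > 0L) {
    rlang::abort(paste0("manifest is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  if (!"exclusion_reason" %in% names(m)) m$exclusion_reason <- NA_character_
  m <- dplyr::mutate(
    m,
    dplyr::across(dplyr::all_of(c("intermediate_index", "deposited_start",
                                  "deposited_end", "modeled_start",
                                  "modeled_end")), as.integer),
    dplyr::across(dplyr::all_of(c("is_native", "excluded")),
                  ~ tolower(.x) %in% c("true", "t", "1", "yes"))
  )
  m <- m[, manifest_cols]
  validate_manifest(m)
}

#' Validate a manifest
#'
#' Checks the manifest invariants: unique (pdb_id, conformation_label,
#' intermediate_index) keys, modeled ranges contained in deposited ranges,
#' and a non-empty reason for every excluded row.
#'
#' @param manifest A manifest tibble.
#' @return The manifest, invisibly validated (errors on violation).
#' @export
validate_manifest <- function(manifest) {
  key <- paste(manifest$pdb_id, manifest$conformation_label,
               manifest$intermediate_index)
  if (anyDuplicated(key)) {
    rlang::abort(paste0("duplicate (pdb_id, conformation_label, ",
                        "intermediate_index): ",
                        paste(unique(key[duplicated(key)]), collapse = "; ")))
  }
  bad <- manifest$modeled_start < manifest$deposited_start |
    manifest$modeled_end > manifest$deposited_end |
    manifest$modeled_start > manifest$modeled_end
  if (any(bad)) {
    rlang::abort(sprintf(
      "modeled_range outside deposited_range for pdb_id: %s",
      paste(manifest$pdb_id[bad], collapse = ", ")
    ))
  }
  noreason <- manifest$excluded &
    (is.na(manifest$exclusion_reason) |
       !nzchar(trimws(manifest$exclusion_reason)))
  if (any(noreason)) {
    rlang::abort("excluded rows must carry a non-empty exclusion_reason")
  }
  manifest
}

#' Write a manifest to TSV
#'
#' @param manifest A manifest tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  readr::write_tsv(manifest, path, progress = FALSE)
  invisible(path)
}

#' Path to the packaged co-translational catalogue fixture
#'
#' A manifest encoding the published record of experimentally determined
#' co-translational folding intermediates: four studies, 11 intermediates and
#' 17 conformations, six of which have modeled ranges shorter than their
#' deposited ranges and two of which (PDB ids 70II and 5B3Y) are excluded for
#' major modeled-vs-deposited discrepancies. Study-level structure (ranges,
#' counts, native positions, shared multi-model depositions) follows the
#' primary literature; per-conformation PDB ids that are not public in the
#' main record use synthetic placeholder codes (9AX1...), hence the
#' `_synthetic` file name.
#'
#' @return File path of the TSV fixture.
#' @export
cotranslational_catalogue <- function() {
  system.file("extdata", "cotranslational_catalogue_synthetic.tsv",
              package = "nascentfold", mustWork = TRUE)
}

#' Curate a manifest
#'
#' Drops rows flagged as excluded (conformations whose modeled range deviates
#' too much from the deposited range to support structural comparison) and
#' summarizes what is retained.
#'
#' @param manifest A manifest tibble.
#' @return List with `retained` (the curated manifest) and `summary`, a
#'   one-row tibble of catalogue/retention counts.
#' @export
curate_manifest <- function(manifest) {
  validate_manifest(manifest)
  retained <- dplyr::filter(manifest, !.data$excluded)
  if (nrow(retained) == 0L) rlang::warn("all manifest rows are excluded")
  n_int <- function(m) {
    nrow(dplyr::distinct(m, .data$protein_id, .data$intermediate_index))
  }
  list(
    retained = retained,
    summary = tibble::tibble(
      n_conformations_catalogued = nrow(manifest),
      n_conformations_retained = nrow(retained),
      n_intermediates_catalogued = n_int(manifest),
      n_intermediates_retained = n_int(retained),
      n_excluded = sum(manifest$excluded),
      n_studies = length(unique(manifest$study))
    )
  )
}
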