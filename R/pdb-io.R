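#' Read conformations from a PDB file
#'
#' Parses ATOM records via [bio3d::read.pdb()], returning one conformation
#' per MODEL block (NMR-style ensembles such as multi-conformation nascent
#' chain depositions) or only the first. Only the selected chain is kept —
#' chain selection is how attached entities (ribosome, fusion partners) are
#' excluded from analysis. Alternate locations are resolved to the highest
#' occupancy (ties broken by altloc letter order); insertion codes are not
#' supported and raise an error. Residues without a C-alpha atom are dropped
#' with a warning.
#'
#' @param path PDB file path.
#' @param model_policy `"all"` (one conformation per model) or `"first"`.
#' @param chain Chain identifier; default the first chain in the file.
#' @param protein_id Protein id for the conformations; defaults to the file
#'   name without extension.
#' @return List of `conformation` objects.
#' @export
read_structure <- function(path, model_policy = c("all", "first"),
                           chain = NULL, protein_id = NULL) {
  model_policy <- match.arg(model_policy)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  full <- pdb$atom
  rows <- which(full$type == "ATOM")  # row indices into the full atom table
  if (length(rows) == 0L) rlang::abort("no ATOM records in file")
  chain <- chain %||% full$chain[rows[1]]
  rows <- rows[full$chain[rows] %in% chain]
  if (length(rows) == 0L) rlang::abort(sprintf("chain '%s' not found", chain))
  at <- full[rows, , drop = FALSE]
  if (any(!is.na(at$insert) & at$insert != "")) {
    rlang::abort("insertion codes are not supported")
  }
  # altloc: highest occupancy per (residue, atom name), ties by letter order
  alt <- at$alt
  alt[is.na(alt)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1
  ord <- order(paste(at$resno, at$elety), -occ, alt)
  at_ord <- at[ord, , drop = FALSE]
  sel <- !duplicated(paste(at_ord$resno, at_ord$elety))
  at <- at_ord[sel, , drop = FALSE]
  keep <- rows[ord][sel]  # into the full atom table, aligned with `at`

  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_models <- nrow(xyz)
  if (n_models == 0L) rlang::abort("zero models in file")
  models <- if (model_policy == "first") 1L else seq_len(n_models)

  ca_rows <- which(at$elety == "CA")
  resno_all <- sort(unique(at$resno))
  resno_ca <- sort(at$resno[ca_rows])
  missing_ca <- setdiff(resno_all, resno_ca)
  if (length(missing_ca) > 0L) {
    rlang::warn(sprintf("dropping %d residue(s) without a C-alpha atom: %s",
                        length(missing_ca),
                        paste(missing_ca, collapse = ", ")))
  }
  ca_rows <- ca_rows[order(at$resno[ca_rows])]
  aa <- bio3d::aa321(at$resid[ca_rows])
  protein_id <- protein_id %||% tools::file_path_sans_ext(basename(path))

  lab <- function(m) {
    if (length(models) == 1L) "a"
    else if (m <= 26L) letters[m]
    else as.character(m)
  }
  lapply(models, function(m) {
    col_idx <- function(rows) as.vector(rbind(3 * keep[rows] - 2,
                                              3 * keep[rows] - 1,
                                              3 * keep[rows]))
    ca_xyz <- matrix(xyz[m, col_idx(ca_rows)], ncol = 3, byrow = TRUE)
    atoms <- NULL
    other <- setdiff(seq_len(nrow(at)), ca_rows)
    other <- other[at$resno[other] %in% at$resno[ca_rows]]
    if (length(other) > 0L) {
      oxyz <- matrix(xyz[m, col_idx(other)], ncol = 3, byrow = TRUE)
      atoms <- tibble::tibble(
        seq_index = as.integer(at$resno[other]),
        elety = at$elety[other],
        x = oxyz[, 1], y = oxyz[, 2], z = oxyz[, 3]
      )
    }
    new_conformation(
      tibble::tibble(seq_index = as.integer(at$resno[ca_rows]), aa = aa,
                     x = ca_xyz[, 1], y = ca_xyz[, 2], z = ca_xyz[, 3]),
      protein_id = protein_id,
      conformation_label = lab(m),
      atoms = atoms
    )
  })
}

#' Write conformations to a PDB file
#'
#' Emits a C-alpha-trace PDB file. A list with more than one conformation is
#' written as an NMR-style multi-model file (MODEL/ENDMDL blocks), so that
#' `read_structure(write_structure(x))` reproduces residue numbering,
#' amino-acid codes and coordinates to PDB precision (3 decimals).
#'
#' @param conformations A `conformation` or non-empty list of conformations
#'   sharing one `protein_id`.
#' @param path Output file path.
#' @param chain Chain identifier written into the records.
#' @return `path`, invisibly.
#' @export
write_structure <- function(conformations, path, chain = "A") {
  if (inherits(conformations, "conformation")) {
    conformations <- list(conformations)
  }
  if (length(conformations) == 0L) rlang::abort("empty conformation list")
  pids <- unique(vapply(conformations, conf_protein_id, character(1)))
  if (length(pids) > 1L) {
    rlang::abort("conformations must share a protein_id")
  }
  multi <- length(conformations) > 1L
  lines <- character(0)
  for (m in seq_along(conformations)) {
    conf <- conformations[[m]]
    if (multi) lines <- c(lines, sprintf("MODEL     %4d", m))
    res3 <- bio3d::aa123(conf$aa)
    lines <- c(lines, sprintf(
      "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
      seq_len(nrow(conf)), res3, chain, conf$seq_index,
      conf$x, conf$y, conf$z, 1, 0
    ))
    if (multi) lines <- c(lines, "ENDMDL")
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}
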