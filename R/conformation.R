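#' Construct a conformation
#'
#' A conformation is one 3D structural state of a (possibly partial) protein
#' chain: a tibble with one residue per row and columns `seq_index` (author
#' residue number, 1-based), `aa` (one-letter amino-acid code) and `x`, `y`,
#' `z` (C-alpha coordinates in Angstrom). Chain-level metadata (protein id,
#' time index along a folding pathway, conformation label, deposited and
#' modeled sequence ranges, native flag) travels as attributes so the object
#' still behaves as an ordinary tibble in dplyr pipelines.
#'
#' @param residues Data frame with columns `seq_index`, `aa`, `x`, `y`, `z`.
#' @param protein_id Character scalar identifying the protein.
#' @param intermediate_index Integer time index along the pathway (>= 0).
#' @param conformation_label Label distinguishing conformations of the same
#'   intermediate (e.g. `"a"`, `"b"`, `"c"`).
#' @param deposited_range Inclusive integer pair: the reported sequence range.
#'   Defaults to the modeled range.
#' @param modeled_range Inclusive integer pair: the range actually carrying
#'   coordinates. Defaults to `range(seq_index)`.
#' @param is_native Logical: is this the native (final) structure?
#' @param atoms Optional tibble of additional atom records with columns
#'   `seq_index`, `elety`, `x`, `y`, `z`, used by any-atom contact rules.
#' @return A `conformation` tibble.
#' @export
new_conformation <- function(residues, protein_id,
                             intermediate_index = 0L,
                             conformation_label = "a",
                             deposited_range = NULL,
                             modeled_range = NULL,
                             is_native = FALSE,
                             atoms = NULL) {
  residues <- tibble::as_tibble(residues)
  needed <- c("seq_index", "aa", "x", "y", "z")
  if (!all(needed %in% names(residues))) {
    rlang::abort(paste0("residues must have columns: ",
                        paste(needed, collapse = ", ")))
  }
  residues$seq_index <- as.integer(residues$seq_index)
  if (nrow(residues) == 0L) rlang::abort("a conformation needs >= 1 residue")
  if (any(!is.finite(residues$x) | !is.finite(residues$y) |
            !is.finite(residues$z))) {
    rlang::abort("C-alpha coordinates must be finite")
  }
  if (any(residues$seq_index < 1L)) rlang::abort("seq_index must be >= 1")
  if (is.unsorted(residues$seq_index, strictly = TRUE)) {
    rlang::abort("residue seq_index must be strictly increasing")
  }
  if (is.null(modeled_range)) modeled_range <- range(residues$seq_index)
  modeled_range <- as.integer(modeled_range)
  if (is.null(deposited_range)) deposited_range <- modeled_range
  deposited_range <- as.integer(deposited_range)
  if (modeled_range[1] < deposited_range[1] ||
        modeled_range[2] > deposited_range[2]) {
    rlang::abort("modeled_range must lie within deposited_range")
  }
  if (any(residues$seq_index < deposited_range[1]) ||
        any(residues$seq_index > deposited_range[2])) {
    rlang::abort("every residue seq_index must lie within deposited_range")
  }
  structure(
    residues,
    class = c("conformation", class(tibble::tibble())),
    protein_id = as.character(protein_id),
    intermediate_index = as.integer(intermediate_index),
    conformation_label = as.character(conformation_label),
    deposited_range = deposited_range,
    modeled_range = modeled_range,
    is_native = isTRUE(is_native),
    atoms = atoms
  )
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf(
    "<conformation> %s  intermediate %d%s  %d residues  modeled %d-%d%s\n",
    attr(x, "protein_id"), attr(x, "intermediate_index"),
    attr(x, "conformation_label"), nrow(x),
    attr(x, "modeled_range")[1], attr(x, "modeled_range")[2],
    if (isTRUE(attr(x, "is_native"))) "  (native)" else ""
  ))
  NextMethod()
}

#' Conformation accessors
#'
#' @param conf A `conformation`.
#' @return `conf_coords()` returns the n x 3 matrix of C-alpha coordinates
#'   (rows named by `seq_index`); the others return the corresponding
#'   metadata attribute.
#' @export
conf_coords <- function(conf) {
  m <- cbind(conf$x, conf$y, conf$z)
  rownames(m) <- conf$seq_index
  m
}

#' @rdname conf_coords
#' @export
conf_protein_id <- function(conf) attr(conf, "protein_id")

#' @rdname conf_coords
#' @export
conf_label <- function(conf) attr(conf, "conformation_label")

#' @rdname conf_coords
#' @export
conf_intermediate_index <- function(conf) attr(conf, "intermediate_index")

#' @rdname conf_coords
#' @export
conf_is_native <- function(conf) isTRUE(attr(conf, "is_native"))

#' @rdname conf_coords
#' @export
conf_modeled_range <- function(conf) attr(conf, "modeled_range")

#' @rdname conf_coords
#' @export
conf_deposited_range <- function(conf) attr(conf, "deposited_range")

# short id used in comparison records
conf_id <- function(conf) {
  sprintf("%s/%d%s", conf_protein_id(conf), conf_intermediate_index(conf),
          conf_label(conf))
}

# replace the coordinate columns, keeping metadata
set_coords <- function(conf, m) {
  conf$x <- m[, 1]
  conf$y <- m[, 2]
  conf$z <- m[, 3]
  conf
}

# prefix of the first n residues in modeled order, keeping metadata
conf_prefix <- function(conf, n, intermediate_index = NULL,
                        is_native = NULL) {
  res <- tibble::as_tibble(conf)[seq_len(n), ]
  new_conformation(
    res,
    protein_id = conf_protein_id(conf),
    intermediate_index = intermediate_index %||%
      conf_intermediate_index(conf),
    conformation_label = conf_label(conf),
    deposited_range = c(conf_deposited_range(conf)[1], max(res$seq_index)),
    modeled_range = range(res$seq_index),
    is_native = is_native %||% FALSE
  )
}

#' Map residues shared by two conformations
#'
#' Residue correspondence is by author residue number (`seq_index`), never by
#' position, so partial chains (e.g. a 1-27 nascent-chain conformation vs the
#' 1-70 conformation of a later intermediate) map onto their shared residues.
#'
#' @param a,b Conformations of the same protein.
#' @return Tibble with columns `seq_index`, `idx_a`, `idx_b` (row indices into
#'   `a` and `b`), ascending in `seq_index`. Zero rows if the modeled ranges
#'   are disjoint.
#' @export
map_common_residues <- function(a, b) {
  if (!identical(conf_protein_id(a), conf_protein_id(b))) {
    rlang::abort("conformations must belong to the same protein_id")
  }
  shared <- sort(intersect(a$seq_index, b$seq_index))
  tibble::tibble(
    seq_index = shared,
    idx_a = match(shared, a$seq_index),
    idx_b = match(shared, b$seq_index)
  )
}

#' Assemble conformations into a folding pathway
#'
#' A pathway is a nested tibble: one row per conformation, columns
#' `intermediate_index`, `conformation_label` and a `conformation`
#' list-column, ordered by time. Co-translational pathways are expected to
#' carry nested prefix ranges (fixed start, non-decreasing end); violations
#' set the `nested_prefixes` attribute to `FALSE` with a warning rather than
#' failing, because experimentally catalogued pathways (e.g. a native
#' deposited before a longer ribosome-bound construct) can break the idealized
#' ordering.
#'
#' @param conformations List of `conformation` objects (same protein).
#' @param protein_id Optional; defaults to the conformations' shared id.
#' @param validate Check ordering invariants (default `TRUE`).
#' @return A `pathway` tibble.
#' @export
new_pathway <- function(conformations, protein_id = NULL, validate = TRUE) {
  if (length(conformations) == 0L) rlang::abort("empty pathway")
  pids <- unique(vapply(conformations, conf_protein_id, character(1)))
  if (length(pids) > 1L) {
    rlang::abort("all conformations in a pathway must share protein_id")
  }
  protein_id <- protein_id %||% pids
  idx <- vapply(conformations, conf_intermediate_index, integer(1))
  ord <- order(idx, vapply(conformations, conf_label, character(1)))
  conformations <- conformations[ord]
  idx <- idx[ord]
  nested <- TRUE
  if (validate) {
    uidx <- unique(idx)
    starts <- vapply(conformations, function(c) conf_deposited_range(c)[1],
                     integer(1))
    ends <- vapply(conformations, function(c) conf_deposited_range(c)[2],
                   integer(1))
    if (length(unique(starts)) > 1L || is.unsorted(ends)) {
      nested <- FALSE
      rlang::warn("deposited ranges are not nested prefixes along the pathway")
    }
    native <- vapply(conformations, conf_is_native, logical(1))
    if (any(native) && !all(idx[native] == max(idx))) {
      rlang::warn("a native conformation is not at the last time index")
    }
  }
  structure(
    tibble::tibble(
      intermediate_index = idx,
      conformation_label = vapply(conformations, conf_label, character(1)),
      conformation = conformations
    ),
    class = c("pathway", class(tibble::tibble())),
    protein_id = protein_id,
    nested_prefixes = nested
  )
}

#' @export
print.pathway <- function(x, ...) {
  cat(sprintf("<pathway> %s  %d intermediates, %d conformations\n",
              attr(x, "protein_id"),
              length(unique(x$intermediate_index)), nrow(x)))
  NextMethod()
}

#' @rdname conf_coords
#' @param pathway A `pathway`.
#' @export
pathway_protein_id <- function(pathway) attr(pathway, "protein_id")

# one conformation per intermediate, in time order; errors otherwise
pathway_snapshots <- function(pathway) {
  tab <- table(pathway$intermediate_index)
  if (any(tab > 1L)) {
    rlang::abort(paste0(
      "intermediate(s) with multiple conformations: ",
      paste(names(tab)[tab > 1L], collapse = ", "),
      "; select one conformation per intermediate first"
    ))
  }
  pathway$conformation
}

`%||%` <- function(a, b) if (is.null(a)) b else a
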