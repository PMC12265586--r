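#' Contact-rule parameters for protein structure networks
#'
#' A PSN joins two amino-acid nodes by an edge when they are close enough in
#' the 3D structure. "Close enough" defaults to a C-alpha distance of at most
#' 6.0 Angstrom (a common PSN convention) with all non-self pairs eligible;
#' the any-atom rule (minimum inter-residue atom distance, default cutoff
#' 4.0 Angstrom) requires full atom records.
#'
#' @param contact_mode `"ca"` or `"any_atom"`.
#' @param cutoff Contact distance cutoff in Angstrom; defaults to 6.0 for
#'   `"ca"` and 4.0 for `"any_atom"`.
#' @param min_sequence_separation Minimum `|i - j|` in residue numbering for
#'   an eligible pair (>= 1; 1 means all non-self pairs).
#' @return A `psn_params` list.
#' @export
psn_params <- function(contact_mode = c("ca", "any_atom"), cutoff = NULL,
                       min_sequence_separation = 1L) {
  contact_mode <- match.arg(contact_mode)
  cutoff <- cutoff %||% if (contact_mode == "ca") 6.0 else 4.0
  if (cutoff <= 0) rlang::abort("cutoff must be > 0")
  min_sequence_separation <- as.integer(min_sequence_separation)
  if (min_sequence_separation < 1L) {
    rlang::abort("min_sequence_separation must be >= 1")
  }
  structure(list(contact_mode = contact_mode, cutoff = cutoff,
                 min_sequence_separation = min_sequence_separation),
            class = "psn_params")
}

# residue contact pairs (seq_index values, i < j) under a psn_params rule
.contact_pairs <- function(conf, params) {
  si <- conf$seq_index
  n <- length(si)
  if (n < 2L) return(cbind(i = integer(0), j = integer(0)))
  if (params$contact_mode == "ca") {
    d <- as.matrix(stats::dist(conf_coords(conf)))
    sep <- abs(outer(si, si, `-`))
    hit <- which(d <= params$cutoff & sep >= params$min_sequence_separation &
                   upper.tri(d), arr.ind = TRUE)
    cbind(i = si[hit[, 1]], j = si[hit[, 2]])
  } else {
    atoms <- attr(conf, "atoms")
    if (is.null(atoms)) {
      rlang::abort("any_atom contact mode requires atom records")
    }
    all_atoms <- dplyr::bind_rows(
      tibble::tibble(seq_index = si, x = conf$x, y = conf$y, z = conf$z),
      atoms[, c("seq_index", "x", "y", "z")]
    )
    d <- as.matrix(stats::dist(cbind(all_atoms$x, all_atoms$y, all_atoms$z)))
    res <- all_atoms$seq_index
    out <- matrix(integer(0), ncol = 2)
    for (a in seq_len(n - 1L)) {
      for (b in (a + 1L):n) {
        if (abs(si[a] - si[b]) < params$min_sequence_separation) next
        if (min(d[res == si[a], res == si[b]]) <= params$cutoff) {
          out <- rbind(out, c(si[a], si[b]))
        }
      }
    }
    colnames(out) <- c("i", "j")
    out
  }
}

#' Build a protein structure network from a conformation
#'
#' @param conf A `conformation`.
#' @param params A [psn_params()] contact rule.
#' @param snapshot_index Optional snapshot position (set by
#'   [build_dynamic_psn()]).
#' @return A `psn`: sorted `nodes` (seq_index values), `edges` tibble
#'   (`i < j`, by seq_index), `snapshot_index`, and the contact `params`.
#' @export
build_psn <- function(conf, params = psn_params(), snapshot_index = NA_integer_) {
  pairs <- .contact_pairs(conf, params)
  structure(
    list(nodes = sort(conf$seq_index),
         edges = tibble::tibble(i = as.integer(pairs[, "i"]),
                                j = as.integer(pairs[, "j"])),
         snapshot_index = as.integer(snapshot_index),
         params = params),
    class = "psn"
  )
}

#' @export
print.psn <- function(x, ...) {
  cat(sprintf("<psn> %d nodes, %d edges (%s <= %.1f A, sep >= %d)%s\n",
              length(x$nodes), nrow(x$edges), x$params$contact_mode,
              x$params$cutoff, x$params$min_sequence_separation,
              if (is.na(x$snapshot_index)) ""
              else sprintf(", snapshot %d", x$snapshot_index)))
  invisible(x)
}

#' Adjacency matrix of a PSN
#'
#' @param psn A `psn`.
#' @return Symmetric 0/1 matrix over `psn$nodes` (dimnames = seq_index).
#' @export
psn_adjacency <- function(psn) {
  n <- length(psn$nodes)
  a <- matrix(0L, n, n, dimnames = list(psn$nodes, psn$nodes))
  if (nrow(psn$edges) > 0L) {
    ii <- match(psn$edges$i, psn$nodes)
    jj <- match(psn$edges$j, psn$nodes)
    a[cbind(ii, jj)] <- 1L
    a[cbind(jj, ii)] <- 1L
  }
  a
}

#' Build a dynamic PSN from a folding pathway
#'
#' One network snapshot per pathway intermediate (each intermediate must hold
#' exactly one conformation). For proxy-derived pathways the snapshots are
#' nested (`V_t` within `V_t+1`, `E_t` within `E_t+1`) because every snapshot
#' is cut from the same static native structure; the nesting is validated and
#' recorded in the `nested` field, not forced, so genuinely dynamic pathways
#' (whose conformations move between time points) simply carry `nested =
#' FALSE`.
#'
#' @param pathway A `pathway` with one conformation per intermediate.
#' @param params A [psn_params()] contact rule.
#' @return A `dynamic_psn`: list of `snapshots` plus the `nested` flag.
#' @export
build_dynamic_psn <- function(pathway, params = psn_params()) {
  confs <- pathway_snapshots(pathway)
  snaps <- lapply(seq_along(confs), function(t) {
    build_psn(confs[[t]], params, snapshot_index = t)
  })
  nested <- TRUE
  if (length(snaps) > 1L) {
    ekey <- function(p) paste(p$edges$i, p$edges$j)
    for (t in seq_len(length(snaps) - 1L)) {
      if (!all(snaps[[t]]$nodes %in% snaps[[t + 1L]]$nodes) ||
            !all(ekey(snaps[[t]]) %in% ekey(snaps[[t + 1L]]))) {
        nested <- FALSE
        break
      }
    }
  }
  structure(list(snapshots = snaps, nested = nested), class = "dynamic_psn")
}

#' @export
print.dynamic_psn <- function(x, ...) {
  cat(sprintf("<dynamic_psn> %d snapshots (%s), nodes %s\n",
              length(x$snapshots),
              if (x$nested) "nested" else "not nested",
              paste(vapply(x$snapshots, function(p) length(p$nodes),
                           integer(1)), collapse = ", ")))
  invisible(x)
}

graphlet_classes <- c("edge", "two_path", "triangle", "three_path",
                      "three_star", "four_cycle", "tailed_triangle",
                      "diamond", "four_clique")

#' Count connected induced graphlets on 2-4 nodes
#'
#' Counts the 9 connected induced subgraph classes on 2, 3 and 4 nodes (edge;
#' 2-path; triangle; 3-path; 3-star; 4-cycle; tailed triangle; diamond;
#' 4-clique) exactly, via closed-form adjacency-matrix combinatorics:
#' non-induced pattern counts (degree/triangle/common-neighbour sums and the
#' trace of A^4) are converted to induced counts by inclusion-exclusion over
#' the 4-node superpattern lattice. Deterministic and equivalent to
#' exhaustive enumeration of connected node subsets.
#'
#' @param psn A `psn`.
#' @return A `graphlet_vector`: named `counts` (9 non-negative integers) and
#'   `frequencies` (counts normalized to sum 1; all-zero if no graphlets).
#' @export
count_graphlets <- function(psn) {
  a <- psn_adjacency(psn)
  n <- nrow(a)
  counts <- stats::setNames(numeric(9), graphlet_classes)
  if (n >= 2L && sum(a) > 0) {
    storage.mode(a) <- "double"
    deg <- rowSums(a)
    m <- sum(deg) / 2
    a2 <- a %*% a
    tri_i <- diag(a2 %*% a) / 2           # triangles at each node
    tri <- sum(tri_i) / 3
    ei <- which(a == 1 & upper.tri(a), arr.ind = TRUE)
    cn <- a2[ei]                           # common neighbours per edge

    p4_non <- sum((deg[ei[, 1]] - 1) * (deg[ei[, 2]] - 1) - cn)
    claw_non <- sum(choose(deg, 3))
    c4_non <- (sum(a2 * a2) - sum(deg * (2 * deg - 1))) / 8
    paw_non <- sum(tri_i * (deg - 2))
    diamond_non <- sum(choose(cn, 2))
    k4 <- 0
    for (e in seq_len(nrow(ei))) {
      com <- which(a[ei[e, 1], ] == 1 & a[ei[e, 2], ] == 1)
      if (length(com) >= 2L) k4 <- k4 + sum(a[com, com]) / 2
    }
    k4 <- k4 / 6

    diamond <- diamond_non - 6 * k4
    c4 <- c4_non - diamond - 3 * k4
    paw <- paw_non - 4 * diamond - 12 * k4
    claw <- claw_non - paw - 2 * diamond - 4 * k4
    p4 <- p4_non - 2 * paw - 4 * c4 - 6 * diamond - 12 * k4

    counts[] <- round(c(m, sum(choose(deg, 2)) - 3 * tri, tri,
                        p4, claw, c4, paw, diamond, k4))
  }
  total <- sum(counts)
  structure(
    list(counts = counts,
         frequencies = if (total > 0) counts / total else counts),
    class = "graphlet_vector"
  )
}

#' @export
print.graphlet_vector <- function(x, ...) {
  print(x$counts)
  invisible(x)
}

#' Static graphlet features of a PSN
#'
#' @param psn A `psn`.
#' @return Named numeric vector: the 9 graphlet frequencies.
#' @export
static_features <- function(psn) {
  count_graphlets(psn)$frequencies
}

#' Dynamic graphlet features of a dynamic PSN
#'
#' A per-snapshot feature scheme for folding pathways: snapshots are
#' resampled to `n_bins` time bins by nearest position (no interpolation of
#' graphs), each bin contributing its snapshot's 9 graphlet frequencies, and
#' a 9-entry arrival histogram records the normalized snapshot (t / n) at
#' which each graphlet class first appears (1.0 if it never does). The
#' binning normalizes pathway length so pathways with different numbers of
#' intermediates are comparable.
#'
#' @param dpsn A `dynamic_psn` (>= 1 snapshot).
#' @param n_bins Number of time bins (>= 1, default 10).
#' @return Named numeric vector of length `9 * n_bins + 9`.
#' @export
dynamic_features <- function(dpsn, n_bins = 10L) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) rlang::abort("n_bins must be >= 1")
  s <- length(dpsn$snapshots)
  if (s < 1L) rlang::abort("dynamic PSN has no snapshots")
  gl <- lapply(dpsn$snapshots, count_graphlets)
  pick <- pmin(pmax(round(seq_len(n_bins) / n_bins * s), 1L), s)
  binned <- unlist(lapply(seq_len(n_bins), function(b) {
    stats::setNames(gl[[pick[b]]]$frequencies,
                    paste0(graphlet_classes, "_bin", b))
  }))
  arrival <- vapply(graphlet_classes, function(cl) {
    first <- which(vapply(gl, function(g) g$counts[[cl]] > 0, logical(1)))
    if (length(first) == 0L) 1 else first[1] / s
  }, numeric(1))
  names(arrival) <- paste0(graphlet_classes, "_arrival")
  c(binned, arrival)
}
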