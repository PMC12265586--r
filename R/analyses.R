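comparison_record <- function(mode, a, b, tmres) {
  tibble::tibble(
    protein_id = conf_protein_id(a),
    mode = mode,
    conf_a = conf_id(a),
    conf_b = conf_id(b),
    n_mapped = tmres$n_mapped,
    tm = tmres$tm,
    band = similarity_band(tmres$tm)
  )
}

comparison_modes <- c("same_intermediate", "across_time_consecutive",
                      "across_time_distant", "prediction_vs_experiment",
                      "proxy_vs_experiment")

#' Compare distinct conformations of the same intermediate
#'
#' Scores every unordered pair of conformations reported for one folding
#' intermediate (e.g. the a/b/c conformations of a nascent-chain
#' deposition) with [tm_score()] under common-residue normalization.
#'
#' @param conformations List of >= 2 conformations sharing `protein_id` and
#'   `intermediate_index`.
#' @param normalization Passed to [tm_score()].
#' @return Tibble of comparison records (`mode = "same_intermediate"`).
#' @export
compare_same_intermediate <- function(conformations,
                                      normalization = "common") {
  if (length(conformations) < 2L) {
    rlang::abort("need >= 2 conformations to compare")
  }
  idx <- unique(vapply(conformations, conf_intermediate_index, integer(1)))
  pid <- unique(vapply(conformations, conf_protein_id, character(1)))
  if (length(idx) > 1L || length(pid) > 1L) {
    rlang::abort("conformations must share protein_id and intermediate_index")
  }
  pairs <- utils::combn(length(conformations), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(p) {
    a <- conformations[[pairs[1, p]]]
    b <- conformations[[pairs[2, p]]]
    comparison_record("same_intermediate", a, b,
                      tm_score(a, b, normalization))
  })
}

#' Compare conformations of a pathway across time
#'
#' For each ordered pair of time points t < t', maps the earlier
#' intermediate's modeled residues onto the later conformation (the shared
#' subsequence whose structure may have changed as further residues were
#' translated) and scores the pair. `distance = "consecutive"` restricts to
#' t' immediately following t; `"all"` also emits time-distant pairs, so the
#' effect of elapsed time on conformational change can be read off the
#' record modes. Pairs sharing fewer than 3 residues are skipped and listed
#' in the `skipped` attribute with a reason.
#'
#' @param pathway A `pathway` with >= 2 intermediates.
#' @param distance `"consecutive"` or `"all"`.
#' @param normalization Passed to [tm_score()].
#' @return Tibble of comparison records with modes
#'   `across_time_consecutive` / `across_time_distant`; skipped pairs in
#'   `attr(, "skipped")`.
#' @export
compare_across_time <- function(pathway, distance = c("consecutive", "all"),
                                normalization = "common") {
  distance <- match.arg(distance)
  times <- sort(unique(pathway$intermediate_index))
  if (length(times) < 2L) rlang::abort("pathway needs >= 2 intermediates")
  skipped <- tibble::tibble(conf_a = character(0), conf_b = character(0),
                            reason = character(0))
  out <- list()
  for (ti in seq_len(length(times) - 1L)) {
    tjs <- if (distance == "consecutive") ti + 1L else (ti + 1L):length(times)
    for (tj in tjs) {
      mode <- if (tj == ti + 1L) "across_time_consecutive"
              else "across_time_distant"
      confs_a <- pathway$conformation[pathway$intermediate_index == times[ti]]
      confs_b <- pathway$conformation[pathway$intermediate_index == times[tj]]
      for (a in confs_a) for (b in confs_b) {
        if (nrow(map_common_residues(a, b)) < 3L) {
          skipped <- dplyr::add_row(skipped, conf_a = conf_id(a),
                                    conf_b = conf_id(b),
                                    reason = "fewer than 3 shared residues")
          next
        }
        out[[length(out) + 1L]] <-
          comparison_record(mode, a, b, tm_score(a, b, normalization))
      }
    }
  }
  res <- if (length(out) > 0L) dplyr::bind_rows(out) else
    comparison_record_empty()
  attr(res, "skipped") <- skipped
  res
}

comparison_record_empty <- function() {
  tibble::tibble(protein_id = character(0), mode = character(0),
                 conf_a = character(0), conf_b = character(0),
                 n_mapped = integer(0), tm = numeric(0), band = character(0))
}

#' Evaluate predicted against experimental conformations
#'
#' Matches externally produced predicted structures (e.g. from a native-
#' structure predictor run per deposited sequence) to experimental
#' conformations by (protein_id, intermediate_index, conformation_label) and
#' scores each matched pair. When several ranked predictions exist for one
#' sequence (a `prediction_rank` attribute on the conformation), the
#' top-ranked one is used by default. Unmatched experimental conformations
#' are reported in the gap tibble, not treated as errors.
#'
#' @param experimental,predicted Lists of conformations. This package never
#'   runs a structure predictor; predictions are inputs.
#' @param use_rank Which prediction rank to score (default 1).
#' @param normalization Passed to [tm_score()].
#' @return List with `records` (mode `prediction_vs_experiment`) and `gaps`.
#' @export
evaluate_predictions <- function(experimental, predicted, use_rank = 1L,
                                 normalization = "common") {
  pred_key <- vapply(predicted, conf_id, character(1))
  pred_rank <- vapply(predicted, function(p) {
    as.integer(attr(p, "prediction_rank") %||% 1L)
  }, integer(1))
  records <- list()
  gaps <- tibble::tibble(conf = character(0), reason = character(0))
  for (e in experimental) {
    hit <- which(pred_key == conf_id(e) & pred_rank == use_rank)
    if (length(hit) == 0L) {
      gaps <- dplyr::add_row(gaps, conf = conf_id(e),
                             reason = sprintf("no rank-%d prediction",
                                              use_rank))
      next
    }
    records[[length(records) + 1L]] <-
      comparison_record("prediction_vs_experiment", e, predicted[[hit[1]]],
                        tm_score(e, predicted[[hit[1]]], normalization))
  }
  list(records = if (length(records) > 0L) dplyr::bind_rows(records) else
         comparison_record_empty(),
       gaps = gaps)
}

#' Evaluate proxy intermediates against experimental conformations
#'
#' Generates the proxy pathway of `native` (prefix substructures, step `k`)
#' and, for each experimental conformation, scores it against the proxy of
#' closest length over their shared residues. Experimental conformations
#' longer than the native are skipped with a reason.
#'
#' @param native The native `conformation`.
#' @param k Proxy step size (default 5).
#' @param experimental List of experimental conformations.
#' @param normalization Passed to [tm_score()].
#' @return Tibble of records (mode `proxy_vs_experiment`); skipped
#'   conformations in `attr(, "skipped")`.
#' @export
evaluate_proxies <- function(native, k = 5L, experimental,
                             normalization = "common") {
  proxies <- generate_proxy_intermediates(native, k)
  skipped <- tibble::tibble(conf = character(0), reason = character(0))
  records <- list()
  for (e in experimental) {
    if (nrow(e) > nrow(native)) {
      skipped <- dplyr::add_row(skipped, conf = conf_id(e),
                                reason = "native shorter than experimental")
      next
    }
    p <- match_proxy(proxies, e)
    records[[length(records) + 1L]] <-
      comparison_record("proxy_vs_experiment", e, p,
                        tm_score(e, p, normalization))
  }
  res <- if (length(records) > 0L) dplyr::bind_rows(records) else
    comparison_record_empty()
  attr(res, "skipped") <- skipped
  res
}

#' Contact order of a conformation
#'
#' Average sequence separation `|i - j|` of residue pairs in contact —
#' higher contact order means more long-range native contacts and correlates
#' with slower two-state folding. Contacts default to C-alpha distance <=
#' 6 Angstrom with `|i - j| >= 2` (excluding backbone neighbours).
#'
#' @param conf A `conformation` (>= 2 residues).
#' @param cutoff Contact cutoff (Angstrom).
#' @param min_sequence_separation Minimum `|i - j|` (default 2).
#' @return One-row tibble: `n_contacts`, `absolute_co` (residues),
#'   `relative_co` (`absolute_co` / number of residues); the contact-order
#'   columns are `NA` when no contacts exist.
#' @export
contact_order <- function(conf, cutoff = 6.0, min_sequence_separation = 2L) {
  if (nrow(conf) < 2L) rlang::abort("need >= 2 residues")
  pairs <- .contact_pairs(conf, psn_params("ca", cutoff,
                                           min_sequence_separation))
  n <- nrow(pairs)
  sep <- if (n > 0L) abs(pairs[, "i"] - pairs[, "j"]) else numeric(0)
  tibble::tibble(
    n_contacts = n,
    absolute_co = if (n > 0L) mean(sep) else NA_real_,
    relative_co = if (n > 0L) mean(sep) / nrow(conf) else NA_real_
  )
}

#' Two-state folding statistics over simulated or predicted pathways
#'
#' Tracks, for each pair of secondary-structure elements (SSEs), when the
#' native contacts between them first form along each pathway: the formation
#' time of an SSE pair is the first snapshot at which at least
#' `formation_fraction` of its native inter-SSE contacts are present (a
#' contact is present when both residues exist in the snapshot and are
#' within the cutoff). A pathway folds in a two-state manner when all SSE
#' pairs form their native contacts around the same time — operationally,
#' when the spread (max - min) of formation times is at most `window`
#' snapshots. The two-state fraction is the share of pathways that are
#' two-state, i.e. the probability that the protein exhibits two-state
#' folding kinetics. SSE pairs with no native contacts are excluded from the
#' spread and logged; a pair that never reaches the formation fraction is
#' assigned time `n_snapshots + 1`.
#'
#' @param pathways List of `pathway` objects (one conformation per
#'   intermediate).
#' @param native The native `conformation` defining native contacts.
#' @param sse_annotations Tibble of labelled residue ranges: columns
#'   `label`, `start`, `end` (>= 2 rows). No secondary-structure assignment
#'   algorithm is bundled; annotations are inputs.
#' @param window Snapshot window for "around the same time" (default 1).
#' @param formation_fraction Fraction of an SSE pair's native contacts
#'   required for formation (default 0.5).
#' @param cutoff,min_sequence_separation Contact rule (defaults 6 Angstrom,
#'   `|i - j| >= 2`).
#' @return A `kinetics_report`: `formation_times` (pathway x SSE pair),
#'   `pathway_summary` (spread and two-state flag per pathway),
#'   `two_state_fraction`, and the parameters used.
#' @export
two_state_stats <- function(pathways, native, sse_annotations, window = 1L,
                            formation_fraction = 0.5, cutoff = 6.0,
                            min_sequence_separation = 2L) {
  if (length(pathways) < 1L) rlang::abort("need >= 1 pathway")
  sse <- tibble::as_tibble(sse_annotations)
  if (nrow(sse) < 2L) rlang::abort("need >= 2 SSE ranges")
  nat_pairs <- .contact_pairs(native, psn_params("ca", cutoff,
                                                 min_sequence_separation))
  sse_of <- function(res) {
    hit <- which(sse$start <= res & res <= sse$end)
    if (length(hit) == 0L) NA_character_ else sse$label[hit[1]]
  }
  sa <- vapply(nat_pairs[, "i"], sse_of, character(1))
  sb <- vapply(nat_pairs[, "j"], sse_of, character(1))
  inter <- !is.na(sa) & !is.na(sb) & sa != sb
  pair_id <- ifelse(sa < sb, paste(sa, sb, sep = ":"),
                    paste(sb, sa, sep = ":"))
  contacts <- tibble::tibble(i = nat_pairs[inter, "i"],
                             j = nat_pairs[inter, "j"],
                             sse_pair = pair_id[inter])
  all_pairs <- utils::combn(sort(sse$label), 2)
  all_ids <- paste(all_pairs[1, ], all_pairs[2, ], sep = ":")
  no_contact <- setdiff(all_ids, unique(contacts$sse_pair))
  if (length(no_contact) > 0L) {
    rlang::warn(paste0("SSE pair(s) without native contacts excluded: ",
                       paste(no_contact, collapse = ", ")))
  }
  if (length(unique(contacts$sse_pair)) < 2L) {
    rlang::warn(paste0("only ", length(unique(contacts$sse_pair)),
                       " SSE pair(s) carry native contacts; ",
                       "the two-state criterion is degenerate"))
  }

  ft <- purrr::map_dfr(seq_along(pathways), function(p) {
    snaps <- pathway_snapshots(pathways[[p]])
    s <- length(snaps)
    present <- matrix(FALSE, nrow(contacts), s)
    for (t in seq_len(s)) {
      co <- conf_coords(snaps[[t]])
      si <- snaps[[t]]$seq_index
      ia <- match(contacts$i, si)
      ib <- match(contacts$j, si)
      ok <- !is.na(ia) & !is.na(ib)
      d <- sqrt(rowSums((co[ia[ok], , drop = FALSE] -
                           co[ib[ok], , drop = FALSE])^2))
      present[which(ok)[d <= cutoff], t] <- TRUE
    }
    purrr::map_dfr(split(seq_len(nrow(contacts)), contacts$sse_pair),
                   function(rows) {
      frac <- colMeans(present[rows, , drop = FALSE])
      first <- which(frac >= formation_fraction)
      tibble::tibble(
        pathway = p,
        sse_pair = contacts$sse_pair[rows[1]],
        formation_time = if (length(first) > 0L) first[1] else s + 1L,
        n_snapshots = s
      )
    })
  })
  summary <- ft |>
    dplyr::group_by(.data$pathway) |>
    dplyr::summarise(
      spread = max(.data$formation_time) - min(.data$formation_time),
      .groups = "drop"
    ) |>
    dplyr::mutate(is_two_state = .data$spread <= window)
  structure(
    list(formation_times = ft, pathway_summary = summary,
         two_state_fraction = mean(summary$is_two_state),
         window = window, formation_fraction = formation_fraction),
    class = "kinetics_report"
  )
}

#' @export
print.kinetics_report <- function(x, ...) {
  cat(sprintf(
    "<kinetics_report> %d pathways, two-state fraction = %.3f (window %d)\n",
    nrow(x$pathway_summary), x$two_state_fraction, x$window))
  invisible(x)
}

#' @rdname two_state_stats
#' @param x A `kinetics_report`.
#' @param ... Unused.
#' @export
glance.kinetics_report <- function(x, ...) {
  tibble::tibble(
    n_pathways = nrow(x$pathway_summary),
    n_two_state = sum(x$pathway_summary$is_two_state),
    two_state_fraction = x$two_state_fraction,
    window = x$window,
    formation_fraction = x$formation_fraction
  )
}

#' @rdname two_state_stats
#' @export
tidy.kinetics_report <- function(x, ...) {
  x$formation_times
}
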