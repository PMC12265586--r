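#' Prefix-length schedule for proxy co-translational intermediates
#'
#' Proxy intermediates take the first k, 2k, 3k, ... residues of a native
#' structure; the schedule ends with the full length L exactly (the last
#' proxy captures the entire protein), so when L is not a multiple of k the
#' final entry is L itself and no short remainder-only intermediate is added.
#' The default k = 5 mimics the addition of individual secondary-structure
#' elements during translation.
#'
#' @param l Total residue count (>= 1).
#' @param k Step size in residues (>= 1, default 5).
#' @return A `proxy_schedule`: list with `k`, `l` and integer
#'   `prefix_lengths` (strictly increasing, final entry `l`,
#'   `ceiling(l / k)` entries).
#' @export
proxy_schedule <- function(l, k = 5L) {
  l <- as.integer(l)
  k <- as.integer(k)
  if (l < 1L || k < 1L) rlang::abort("l and k must be >= 1")
  lens <- seq.int(k, by = k, length.out = l %/% k)
  if (length(lens) == 0L || lens[length(lens)] < l) {
    lens <- c(lens, l)
  }
  structure(list(k = k, l = l, prefix_lengths = as.integer(lens)),
            class = "proxy_schedule")
}

#' @export
print.proxy_schedule <- function(x, ...) {
  cat(sprintf("<proxy_schedule> k = %d, L = %d: %s\n", x$k, x$l,
              paste(x$prefix_lengths, collapse = ", ")))
  invisible(x)
}

#' Extract proxy co-translational intermediates from a native structure
#'
#' Each proxy intermediate is the prefix substructure of the native: the
#' first n residues (in modeled order) with coordinates copied unchanged (no
#' re-modelling — proxies are deliberately naive substructures of one static
#' native structure). Prefixes run over modeled residues rather than author
#' residue numbers, so natives with unmodeled gaps still yield well-formed
#' proxies.
#'
#' @param native A `conformation` (>= 1 residue).
#' @param k Step size in residues (default 5).
#' @return A `pathway` whose time index is the schedule position; the last
#'   intermediate is the full native and is flagged native.
#' @export
generate_proxy_intermediates <- function(native, k = 5L) {
  sched <- proxy_schedule(nrow(native), k)
  lens <- sched$prefix_lengths
  confs <- lapply(seq_along(lens), function(t) {
    conf_prefix(native, lens[t], intermediate_index = t,
                is_native = t == length(lens))
  })
  new_pathway(confs, validate = FALSE)
}

#' Match an experimental conformation to its closest proxy intermediate
#'
#' Selects the proxy whose residue count is closest to the target's modeled
#' length; ties break toward the longer proxy. Matching is by length rather
#' than exact range because experimental modeled ranges rarely align to
#' multiples of k.
#'
#' @param proxies A non-empty proxy `pathway`.
#' @param target A `conformation`.
#' @return The matched proxy `conformation`.
#' @export
match_proxy <- function(proxies, target) {
  if (!inherits(proxies, "pathway") || nrow(proxies) == 0L) {
    rlang::abort("proxies must be a non-empty pathway")
  }
  lens <- vapply(proxies$conformation, nrow, integer(1))
  gap <- abs(lens - nrow(target))
  cand <- which(gap == min(gap))
  proxies$conformation[[cand[which.max(lens[cand])]]]
}
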