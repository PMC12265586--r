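# Least-squares rigid superposition via SVD (no degeneracy checks; internal).
# Returns rotation R and translation t such that moving %*% R + t ~ fixed
# (row-vector convention); reflections are excluded (det(R) = +1).
.kabsch <- function(moving, fixed) {
  cm <- colMeans(moving)
  cf <- colMeans(fixed)
  h <- crossprod(sweep(moving, 2, cm), sweep(fixed, 2, cf))
  s <- svd(h)
  d <- sign(det(s$u) * det(s$v))
  if (d == 0) d <- 1
  r <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(rotation = r, translation = as.numeric(cf - cm %*% r))
}

.apply_rigid <- function(coords, fit) {
  sweep(coords %*% fit$rotation, 2, fit$translation, `+`)
}

#' Optimal rigid-body (Kabsch) superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD between two
#' equal-length coordinate sets. Reflections are excluded because chirality
#' is physical: a mirror image of a protein is a different molecule.
#'
#' @param moving,fixed n x 3 coordinate matrices (n >= 3, non-collinear).
#' @return A `superposition` object: `rotation` (3 x 3, det +1),
#'   `translation` (length 3, in the fixed frame), `rmsd`, and
#'   `per_residue_distance` over the n pairs at the optimum.
#' @export
kabsch_superpose <- function(moving, fixed) {
  moving <- as.matrix(moving)
  fixed <- as.matrix(fixed)
  if (!identical(dim(moving), dim(fixed)) || ncol(moving) != 3L) {
    rlang::abort("moving and fixed must be equal-size n x 3 matrices")
  }
  if (nrow(moving) < 3L) rlang::abort("need at least 3 point pairs")
  collinear <- function(x) {
    sv <- svd(sweep(x, 2, colMeans(x)))$d
    sv[2] < 1e-8 * max(sv[1], 1)
  }
  if (collinear(moving) || collinear(fixed)) {
    rlang::abort("degenerate (collinear) geometry")
  }
  fit <- .kabsch(moving, fixed)
  di <- sqrt(rowSums((.apply_rigid(moving, fit) - fixed)^2))
  structure(
    list(rotation = fit$rotation, translation = fit$translation,
         rmsd = sqrt(mean(di^2)), per_residue_distance = di,
         n = nrow(moving)),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> n = %d, rmsd = %.4f A\n", x$n, x$rmsd))
  invisible(x)
}

#' TM-score distance scale d0
#'
#' The length-dependent scale that makes the TM-score length-independent:
#' `d0 = 1.24 * (L - 15)^(1/3) - 1.8`, floored at 0.5 Angstrom so very short
#' fragments (L <= 21, where the formula drops below the floor) remain
#' scorable.
#'
#' @param l_norm Normalization length(s), >= 1.
#' @return d0 in Angstrom (vectorized).
#' @export
compute_d0 <- function(l_norm) {
  if (any(l_norm < 1)) rlang::abort("l_norm must be >= 1")
  raw <- ifelse(l_norm > 15, 1.24 * (l_norm - 15)^(1 / 3) - 1.8, -Inf)
  pmax(0.5, raw)
}

#' TM-score between two conformations
#'
#' Computes the Template Modeling score over the residues shared by the two
#' conformations (mapped by author residue number):
#' `TM = max (1/L_norm) * sum_i 1 / (1 + (d_i/d0)^2)`,
#' maximized over a superposition search. The search seeds Kabsch fits from
#' the full mapped set and from contiguous fragments of lengths n, n/2 and
#' n/4 at every offset; each seed is refined by iteratively re-superposing on
#' the residues closer than `max(d0, 4.5)` Angstrom until the included set is
#' stable (at most 20 iterations), and the best score over all visited
#' superpositions is reported. The reported score is therefore never below
#' the plain global-Kabsch score.
#'
#' Scores lie in (0, 1]: below 0.17 indicates random-like similarity, above
#' 0.3 significant similarity, and above 0.5 the same overall fold.
#'
#' @param target,model Conformations of the same protein with >= 3 shared
#'   residues.
#' @param normalization Length the score is normalized by: `"common"` (the
#'   number of mapped residues; the default, suited to partial-vs-full
#'   nascent-chain comparisons), `"target"` (conventional asymmetric
#'   TM-score) or `"shorter"`.
#' @param max_iter Refinement iteration cap per seed.
#' @return A `tm_result`: `tm`, `normalization_length`, `d0`, `n_mapped`,
#'   `rmsd` and `per_residue_distance` (over all mapped pairs at the
#'   score-optimal superposition), `rotation`, `translation`, `seq_index`.
#' @export
tm_score <- function(target, model,
                     normalization = c("common", "target", "shorter"),
                     max_iter = 20L) {
  normalization <- match.arg(normalization)
  mp <- map_common_residues(target, model)
  n <- nrow(mp)
  if (n < 3L) rlang::abort("fewer than 3 mapped residue pairs")
  xt <- conf_coords(target)[mp$idx_a, , drop = FALSE]
  xm <- conf_coords(model)[mp$idx_b, , drop = FALSE]
  l_norm <- switch(normalization,
    common = n,
    target = nrow(target),
    shorter = min(nrow(target), nrow(model))
  )
  d0 <- compute_d0(l_norm)
  # refinement inclusion cutoffs: the conventional max(d0, 4.5) plus tighter
  # d0-scale cutoffs so small-d0 (short-fragment) optima are reachable
  dcuts <- unique(c(max(d0, 4.5), max(d0, 2), d0))

  seeds <- list(seq_len(n))
  for (lw in unique(c(ceiling(n / 2), max(4L, ceiling(n / 4))))) {
    if (lw >= n || lw < 3L) next
    for (off in seq_len(n - lw + 1L)) {
      seeds[[length(seeds) + 1L]] <- off:(off + lw - 1L)
    }
  }

  best <- list(score = -Inf)
  score_fit <- function(fit) {
    di <- sqrt(rowSums((.apply_rigid(xm, fit) - xt)^2))
    list(score = sum(1 / (1 + (di / d0)^2)) / l_norm, di = di, fit = fit)
  }
  try_subset <- function(idx) {
    fit <- tryCatch(.kabsch(xm[idx, , drop = FALSE],
                            xt[idx, , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    sc <- score_fit(fit)
    if (sc$score > best$score) best <<- sc
    sc
  }
  for (seed in seeds) {
    for (dcut in dcuts) {
      idx <- seed
      for (iter in seq_len(max_iter)) {
        sc <- try_subset(idx)
        if (is.null(sc)) break
        newidx <- which(sc$di < dcut)
        if (length(newidx) < 3L) break
        if (identical(newidx, idx)) break
        idx <- newidx
      }
    }
  }
  # closest-m sweep from the best superposition found: re-superpose on the m
  # best-fitting residues for every m, catching tight small-subset optima
  if (is.finite(best$score)) {
    ord <- order(best$di)
    for (m in 3:n) {
      try_subset(ord[seq_len(m)])
    }
  }
  structure(
    list(tm = best$score, normalization_length = l_norm, d0 = d0,
         n_mapped = n, rmsd = sqrt(mean(best$di^2)),
         per_residue_distance = best$di,
         rotation = best$fit$rotation, translation = best$fit$translation,
         seq_index = mp$seq_index, normalization = normalization),
    class = "tm_result"
  )
}

#' @export
print.tm_result <- function(x, ...) {
  cat(sprintf(
    "<tm_result> tm = %.4f (%s, L_norm = %d, d0 = %.3f A, n_mapped = %d)\n",
    x$tm, x$normalization, x$normalization_length, x$d0, x$n_mapped))
  invisible(x)
}

#' Tidy a TM-score result into per-residue rows
#'
#' @param x A `tm_result`.
#' @param ... Unused.
#' @return Tibble with one mapped residue per row: `seq_index`, `distance`.
#' @export
tidy.tm_result <- function(x, ...) {
  tibble::tibble(seq_index = x$seq_index,
                 distance = x$per_residue_distance)
}

#' One-row summary of a TM-score result
#'
#' @param x A `tm_result`.
#' @param ... Unused.
#' @return One-row tibble: `tm`, `band`, `n_mapped`, `normalization_length`,
#'   `d0`, `rmsd`.
#' @export
glance.tm_result <- function(x, ...) {
  tibble::tibble(tm = x$tm, band = similarity_band(x$tm),
                 n_mapped = x$n_mapped,
                 normalization_length = x$normalization_length,
                 d0 = x$d0, rmsd = x$rmsd)
}

#' Interpret a TM-score as a similarity band
#'
#' Bands partition (0, 1]: `random_like` below 0.17, `intermediate_zone` in
#' \[0.17, 0.3\], `significant` in (0.3, 0.5\] (the 0.5 boundary belongs to
#' the lower band because only scores strictly above 0.5 indicate the same
#' fold), and `same_fold` above 0.5.
#'
#' @param tm TM-score(s) in (0, 1].
#' @return Character vector of band names.
#' @export
similarity_band <- function(tm) {
  if (any(tm <= 0 | tm > 1 + 1e-12)) {
    rlang::abort("TM-scores must lie in (0, 1]")
  }
  dplyr::case_when(
    tm < 0.17 ~ "random_like",
    tm <= 0.3 ~ "intermediate_zone",
    tm <= 0.5 ~ "significant",
    TRUE ~ "same_fold"
  )
}
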