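#' Deterministic ideal-geometry and random-coil chain generators
#'
#' C-alpha-trace generators used throughout the package's tests and examples
#' in place of downloaded structures. `make_helix()` places residues on an
#' ideal alpha-helical spiral (radius 2.30 Angstrom, rise 1.50 A/residue,
#' 100 degrees/residue twist; consecutive C-alpha distance 3.83 A).
#' `make_strand()` is an extended zigzag strand (rise 3.50 A/residue, zigzag
#' half-amplitude chosen so the consecutive C-alpha distance is exactly
#' 3.80 A). `make_coil()` is a seeded self-avoiding random walk with 3.8 A
#' steps. All generators are pure functions of their arguments; the ideal
#' geometries ignore `seed`.
#'
#' @param n Number of residues (>= 1).
#' @param seed Integer seed (used by `make_coil()` only).
#' @param protein_id Protein id for the conformation.
#' @return A `conformation` of `n` residues.
#' @export
make_helix <- function(n, seed = NULL, protein_id = "helix") {
  i <- seq_len(n) - 1
  theta <- i * 100 * pi / 180
  ideal_chain(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i, protein_id)
}

#' @rdname make_helix
#' @export
make_strand <- function(n, seed = NULL, protein_id = "strand") {
  i <- seq_len(n) - 1
  half_amp <- sqrt(3.8^2 - 3.5^2) / 2   # consecutive distance exactly 3.8 A
  ideal_chain(3.5 * i, half_amp * (-1)^i, rep(0, n), protein_id)
}

ideal_chain <- function(x, y, z, protein_id) {
  n <- length(x)
  new_conformation(
    tibble::tibble(seq_index = seq_len(n), aa = rep("A", n),
                   x = x, y = y, z = z),
    protein_id = protein_id
  )
}

#' @rdname make_helix
#' @param min_separation Minimum allowed distance between non-consecutive
#'   C-alpha atoms in the walk (Angstrom).
#' @export
make_coil <- function(n, seed, protein_id = "coil", min_separation = 3.4) {
  withr::with_seed(as.integer(seed), {
    coords <- matrix(0, n, 3)
    dir <- rand_unit()
    if (n > 1L) coords[2, ] <- 3.8 * dir
    i <- 3L
    backtracks <- 0L
    while (i <= n) {
      placed <- FALSE
      for (try in seq_len(200L)) {
        # bend the previous step direction by 20-100 degrees
        cand_dir <- bend_direction(dir, stats::runif(1, 20, 100))
        cand <- coords[i - 1L, ] + 3.8 * cand_dir
        d <- sqrt(rowSums(sweep(coords[seq_len(i - 2L), , drop = FALSE],
                                2, cand)^2))
        if (all(d >= min_separation)) {
          coords[i, ] <- cand
          dir <- cand_dir
          placed <- TRUE
          break
        }
      }
      if (placed) {
        i <- i + 1L
      } else if (i > 3L && backtracks < 100L) {
        backtracks <- backtracks + 1L
        i <- i - 1L
        dir <- coords[i - 1L, ] - coords[i - 2L, ]
        dir <- dir / sqrt(sum(dir^2))
      } else {
        rlang::abort("self-avoiding walk failed to place a residue")
      }
    }
    ideal_chain(coords[, 1], coords[, 2], coords[, 3], protein_id)
  })
}

rand_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# unit vector at `angle_deg` from `dir`, azimuth uniform
bend_direction <- function(dir, angle_deg) {
  ref <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * dir) * dir
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(dir[2] * e1[3] - dir[3] * e1[2],
          dir[3] * e1[1] - dir[1] * e1[3],
          dir[1] * e1[2] - dir[2] * e1[1])
  a <- angle_deg * pi / 180
  phi <- stats::runif(1, 0, 2 * pi)
  cos(a) * dir + sin(a) * (cos(phi) * e1 + sin(phi) * e2)
}

# Rodrigues rotation matrix about unit axis u by angle (degrees)
rotation_about_axis <- function(u, angle_deg) {
  a <- angle_deg * pi / 180
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
               3, 3, byrow = TRUE)
  diag(3) + sin(a) * ux + (1 - cos(a)) * (ux %*% ux)
}

#' Apply a hinge rotation to the tail of a conformation
#'
#' Residues after `hinge_position` are rigidly rotated by `hinge_angle` about
#' the local chain axis (the unit vector from residue `hinge_position - 1` to
#' residue `hinge_position`) through the hinge residue; residues up to the
#' hinge are unchanged, and chain connectivity is preserved exactly because
#' the rotation pivots on the hinge C-alpha. Hinge motions emulate the
#' fold-level conformational changes a nascent-chain subsequence undergoes
#' between time points, while leaving local geometry intact.
#'
#' @param conf A `conformation`.
#' @param hinge_position Residue position (1-based, strictly inside the
#'   chain: `1 < hinge_position < n`).
#' @param hinge_angle Rotation angle in degrees; 0 returns the input
#'   unchanged.
#' @param seed Unused (the operation is deterministic); accepted so hinge
#'   generators share the generator calling convention.
#' @return The hinged `conformation`.
#' @export
make_hinged <- function(conf, hinge_position, hinge_angle, seed = NULL) {
  n <- nrow(conf)
  if (hinge_position <= 1L || hinge_position >= n) {
    rlang::abort("hinge_position must satisfy 1 < hinge_position < n")
  }
  if (hinge_angle == 0) return(conf)
  m <- conf_coords(conf)
  pivot <- m[hinge_position, ]
  axis <- pivot - m[hinge_position - 1L, ]
  axis <- axis / sqrt(sum(axis^2))
  r <- rotation_about_axis(axis, hinge_angle)
  tail_idx <- (hinge_position + 1L):n
  m[tail_idx, ] <- sweep(sweep(m[tail_idx, , drop = FALSE], 2, pivot) %*%
                           t(r), 2, pivot, `+`)
  set_coords(conf, m)
}

#' Simulate a co-translational folding pathway
#'
#' Generates a pathway of nascent-chain intermediates at the proxy schedule's
#' prefix lengths: intermediate t is the native prefix with a persistent
#' hinge inside the first translated segment whose angle,
#' `nonnative_hinge_per_step * (n_snapshots - t)`, decays to zero at the
#' final snapshot — newly added residues join an earlier part that is still
#' non-native, the earlier subsequence relaxes toward its native
#' conformation as translation proceeds (so the conformational change of a
#' shared subsequence grows with time distance), and the last intermediate
#' is exactly the native. With `nonnative_hinge_per_step = 0` the pathway is
#' bit-identical to [generate_proxy_intermediates()].
#'
#' @param native A `conformation` with at least `k` residues.
#' @param k Prefix step size in residues (default 5).
#' @param nonnative_hinge_per_step Hinge magnitude per remaining step,
#'   degrees.
#' @param seed Integer seed (hinge sense per snapshot).
#' @return A `pathway`.
#' @export
simulate_cotranslational_pathway <- function(native, k = 5L,
                                             nonnative_hinge_per_step = 30,
                                             seed = 1L) {
  sched <- proxy_schedule(nrow(native), k)
  lens <- sched$prefix_lengths
  s <- length(lens)
  sign <- withr::with_seed(as.integer(seed), sample(c(-1, 1), 1))
  pos <- if (k >= 3L) max(2L, min(k - 1L, as.integer(ceiling(k / 2)))) else 2L
  confs <- lapply(seq_len(s), function(t) {
    conf <- conf_prefix(native, lens[t], intermediate_index = t,
                        is_native = t == s)
    ang <- nonnative_hinge_per_step * (s - t)
    if (ang > 0 && lens[t] > pos) {
      conf <- make_hinged(conf, pos, sign * ang)
    }
    conf
  })
  new_pathway(confs, validate = FALSE)
}

#' Synthetic classification dataset of folding pathways
#'
#' Builds a balanced two-class set of folding pathways for the static-vs-
#' dynamic network comparison. `"order_only"` classes share one final
#' structure — an asymmetric native whose N-terminal half is a contact-dense
#' helix and whose C-terminal half is a sparse extended strand — and differ
#' only in folding ORDER: class `order_N` folds the helix half first, class
#' `order_C` the strand half first, with the not-yet-folded half held
#' extended. Final snapshots are therefore class-identical up to coordinate
#' jitter (no static signal) while snapshot histories differ (dynamic
#' signal). `"topology"` classes differ in final contact topology instead
#' (helix vs antiparallel-hairpin ladder), with pathways grown as prefix
#' intermediates; both static and dynamic features separate them.
#'
#' @param n_per_class Pathways per class (>= 10, default 50).
#' @param class_specs `"order_only"` or `"topology"`.
#' @param k Prefix step (topology mode) / snapshot count control.
#' @param seed Integer seed.
#' @param l Chain length (default 40).
#' @param jitter_sigma Per-item isotropic coordinate jitter (Angstrom).
#' @return Tibble with one pathway per row: `item`, `label` (factor),
#'   `pathway` (list-column).
#' @export
make_classification_dataset <- function(n_per_class = 50L,
                                        class_specs = c("order_only",
                                                        "topology"),
                                        k = 5L, seed = 1L, l = 40L,
                                        jitter_sigma = 0.3) {
  class_specs <- match.arg(class_specs)
  if (n_per_class < 10L) rlang::abort("n_per_class must be >= 10")
  withr::with_seed(as.integer(seed), {
    if (class_specs == "order_only") {
      labels <- rep(c("order_N", "order_C"), each = n_per_class)
      pathways <- lapply(labels, function(lab) {
        grow_ordered_pathway(order_native(l), from_n = lab == "order_N",
                             n_snapshots = ceiling(l / k),
                             jitter_sigma = jitter_sigma)
      })
    } else {
      labels <- rep(c("helix", "sheet"), each = n_per_class)
      pathways <- lapply(labels, function(lab) {
        native <- if (lab == "helix") make_helix(l, protein_id = "helix")
                  else hairpin_native(l)
        generate_proxy_intermediates(jitter_conf(native, jitter_sigma), k)
      })
    }
    tibble::tibble(item = seq_along(labels), label = factor(labels),
                   pathway = pathways)
  })
}

jitter_conf <- function(conf, sigma) {
  if (sigma <= 0) return(conf)
  m <- conf_coords(conf) + matrix(stats::rnorm(3 * nrow(conf), sd = sigma),
                                  ncol = 3)
  set_coords(conf, m)
}

# asymmetric native: helix half (dense contacts) + displaced strand half
order_native <- function(l) {
  h <- l %/% 2
  helix <- conf_coords(make_helix(h))
  i <- seq_len(l - h) - 1
  half_amp <- sqrt(3.8^2 - 3.5^2) / 2
  strand <- cbind(10 + half_amp * (-1)^i, 0, 30 + 3.5 * i)
  m <- rbind(helix, strand)
  ideal_chain(m[, 1], m[, 2], m[, 3], "order_native")
}

# antiparallel hairpin: two strands 5.28 A apart with alternating rungs
hairpin_native <- function(l) {
  h <- l %/% 2
  half_amp <- sqrt(3.8^2 - 3.5^2) / 2
  i <- seq_len(h) - 1
  out <- cbind(3.5 * i, half_amp * (-1)^i, 0)
  jj <- seq_len(l - h)
  back <- cbind(3.5 * (h - jj), 5.28 + half_amp * (-1)^(h + jj), 0)
  m <- rbind(out, back)
  ideal_chain(m[, 1], m[, 2], m[, 3], "hairpin")
}

# full-length snapshots folding from the N- or C-terminal end; the unfolded
# part is held extended along a ray leaving the folded part
grow_ordered_pathway <- function(native, from_n, n_snapshots, jitter_sigma) {
  l <- nrow(native)
  base <- jitter_conf(native, jitter_sigma)
  m0 <- conf_coords(base)
  confs <- lapply(seq_len(n_snapshots), function(t) {
    n_f <- max(1L, round(t / n_snapshots * l))
    m <- m0
    if (n_f < l) {
      if (from_n) {
        folded <- seq_len(n_f)
        unfolded <- (n_f + 1L):l
        anchor <- m0[n_f, ]
      } else {
        folded <- (l - n_f + 1L):l
        unfolded <- seq.int(l - n_f, 1L)
        anchor <- m0[l - n_f + 1L, ]
      }
      u <- anchor - colMeans(m0[folded, , drop = FALSE])
      nu <- sqrt(sum(u^2))
      u <- if (nu < 1e-8) c(1, 0, 0) else u / nu
      steps <- seq_along(unfolded)
      m[unfolded, ] <- rep(anchor, each = length(steps)) +
        outer(3.8 * steps, u)
    }
    cc <- new_conformation(
      tibble::tibble(seq_index = seq_len(l), aa = rep("A", l),
                     x = m[, 1], y = m[, 2], z = m[, 3]),
      protein_id = conf_protein_id(native),
      intermediate_index = t,
      is_native = t == n_snapshots
    )
    cc
  })
  new_pathway(confs, validate = FALSE)
}
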