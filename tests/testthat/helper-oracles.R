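# Independent oracles and fixture builders used across the suite.

# random proper rotation matrix (uniform-ish; QR of a Gaussian matrix)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# apply a random rigid motion to a conformation
random_rigid_motion <- function(conf) {
  r <- random_rotation()
  t <- stats::rnorm(3, sd = 20)
  nascentfold:::set_coords(conf, sweep(conf_coords(conf) %*% r, 2, t, `+`))
}

# Monte-Carlo lower-bound oracle for the TM-score: best score over n_trials
# random rigid placements of the model (plus the identity placement).
mc_tm_oracle <- function(target, model, n_trials = 10000) {
  mp <- map_common_residues(target, model)
  xt <- conf_coords(target)[mp$idx_a, , drop = FALSE]
  xm <- conf_coords(model)[mp$idx_b, , drop = FALSE]
  n <- nrow(mp)
  d0 <- compute_d0(n)
  ct <- colMeans(xt)
  cm <- colMeans(xm)
  score <- function(moved) {
    di2 <- rowSums((moved - xt)^2)
    sum(1 / (1 + di2 / d0^2)) / n
  }
  best <- score(sweep(sweep(xm, 2, cm), 2, ct, `+`))
  for (i in seq_len(n_trials)) {
    r <- random_rotation()
    shift <- ct + stats::rnorm(3, sd = 2)
    best <- max(best, score(sweep(sweep(xm, 2, cm) %*% r, 2, shift, `+`)))
  }
  best
}

# plain global-Kabsch TM-score (no fragment search, no refinement)
global_kabsch_tm <- function(target, model) {
  mp <- map_common_residues(target, model)
  xt <- conf_coords(target)[mp$idx_a, , drop = FALSE]
  xm <- conf_coords(model)[mp$idx_b, , drop = FALSE]
  fit <- nascentfold:::.kabsch(xm, xt)
  di <- sqrt(rowSums((nascentfold:::.apply_rigid(xm, fit) - xt)^2))
  d0 <- compute_d0(nrow(mp))
  sum(1 / (1 + (di / d0)^2)) / nrow(mp)
}

# exhaustive induced-graphlet oracle: enumerate every 2/3/4-node subset and
# classify the induced subgraph by size, edge count and degree sequence
brute_graphlets <- function(adj) {
  classes <- c("edge", "two_path", "triangle", "three_path", "three_star",
               "four_cycle", "tailed_triangle", "diamond", "four_clique")
  counts <- stats::setNames(numeric(9), classes)
  n <- nrow(adj)
  classify <- function(sub) {
    k <- nrow(sub)
    m <- sum(sub) / 2
    deg <- sort(rowSums(sub))
    # connectivity by reachability
    reach <- diag(k)
    for (s in seq_len(k)) reach <- (reach %*% (sub + diag(k)) > 0) * 1
    if (any(reach[1, ] == 0)) return(NA_character_)
    if (k == 2) return("edge")
    if (k == 3) return(if (m == 2) "two_path" else "triangle")
    if (m == 3) return(if (max(deg) == 3) "three_star" else "three_path")
    if (m == 4) return(if (max(deg) == 3) "tailed_triangle" else "four_cycle")
    if (m == 5) return("diamond")
    "four_clique"
  }
  for (k in 2:min(4, n)) {
    subs <- utils::combn(n, k)
    for (c in seq_len(ncol(subs))) {
      cl <- classify(adj[subs[, c], subs[, c], drop = FALSE])
      if (!is.na(cl)) counts[cl] <- counts[cl] + 1
    }
  }
  counts
}

random_adjacency <- function(n, p) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  a + t(a)
}

psn_from_adjacency <- function(adj) {
  hit <- which(adj == 1 & upper.tri(adj), arr.ind = TRUE)
  structure(
    list(nodes = seq_len(nrow(adj)),
         edges = tibble::tibble(i = as.integer(hit[, 1]),
                                j = as.integer(hit[, 2])),
         snapshot_index = NA_integer_, params = psn_params()),
    class = "psn"
  )
}

# snapshot fixtures for the two-state statistics: full-length conformations
# whose first n_folded residues sit on the native helix and whose remainder
# extends away from the fold
partial_helix <- function(n_folded, l, intermediate_index, pid = "ts") {
  m <- conf_coords(make_helix(l))
  if (n_folded < l) {
    u <- m[n_folded, ] - m[n_folded - 1L, ]
    u <- u / sqrt(sum(u^2))
    for (j in (n_folded + 1L):l) {
      m[j, ] <- m[n_folded, ] + 3.8 * (j - n_folded) * u
    }
  }
  new_conformation(
    tibble::tibble(seq_index = seq_len(l), aa = rep("A", l),
                   x = m[, 1], y = m[, 2], z = m[, 3]),
    protein_id = pid, intermediate_index = intermediate_index
  )
}

extended_chain <- function(l, intermediate_index, pid = "ts") {
  s <- make_strand(l, protein_id = pid)
  attr(s, "intermediate_index") <- as.integer(intermediate_index)
  s
}
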