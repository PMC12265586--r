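collinear_conf <- function(spacing, n = 3) {
  new_conformation(
    tibble::tibble(seq_index = seq_len(n), aa = "A",
                   x = (seq_len(n) - 1) * spacing, y = 0, z = 0),
    protein_id = "line"
  )
}

test_that("contact edges follow the distance cutoff and separation rule", {
  conf <- collinear_conf(3.8)
  p <- build_psn(conf, psn_params("ca", cutoff = 6))
  expect_identical(nrow(p$edges), 2L)
  expect_setequal(paste(p$edges$i, p$edges$j), c("1 2", "2 3"))
  p8 <- build_psn(conf, psn_params("ca", cutoff = 8))
  expect_identical(nrow(p8$edges), 3L)  # d13 = 7.6 <= 8
  single <- nascentfold:::conf_prefix(conf, 1)
  p1 <- build_psn(single)
  expect_identical(length(p1$nodes), 1L)
  expect_identical(nrow(p1$edges), 0L)
  # separation filter
  psep <- build_psn(conf, psn_params("ca", cutoff = 8,
                                     min_sequence_separation = 2))
  expect_identical(nrow(psep$edges), 1L)
  # any_atom requires atom records
  expect_error(build_psn(conf, psn_params("any_atom")), "atom records")
})

test_that("dynamic PSNs from proxies are nested; hinged pathways are flagged", {
  native <- make_helix(12, protein_id = "d")
  pw <- generate_proxy_intermediates(native, 5)
  dp <- build_dynamic_psn(pw)
  expect_length(dp$snapshots, 3)
  expect_identical(vapply(dp$snapshots, function(p) length(p$nodes),
                          integer(1)), c(5L, 10L, 12L))
  expect_true(dp$nested)
  ekey <- function(p) paste(p$edges$i, p$edges$j)
  expect_true(all(ekey(dp$snapshots[[1]]) %in% ekey(dp$snapshots[[2]])))
  expect_true(all(ekey(dp$snapshots[[2]]) %in% ekey(dp$snapshots[[3]])))
  # graphlet counts are monotone along nested snapshots
  counts <- sapply(dp$snapshots, function(p) count_graphlets(p)$counts)
  expect_true(all(apply(counts, 1, function(r) all(diff(r) >= 0))))
  # a genuinely moving pathway loses nesting but builds fine
  moving <- new_pathway(list(
    nascentfold:::conf_prefix(native, 8,  intermediate_index = 1),
    make_hinged(nascentfold:::conf_prefix(native, 12, intermediate_index = 2),
                6, 170)
  ), validate = FALSE)
  expect_false(build_dynamic_psn(moving)$nested)
  # multiple conformations at one time index must be resolved by the caller
  dup <- new_pathway(list(
    nascentfold:::conf_prefix(native, 8, intermediate_index = 1),
    nascentfold:::conf_prefix(native, 8, intermediate_index = 1)
  ), validate = FALSE)
  expect_error(build_dynamic_psn(dup), "multiple conformations")
})

test_that("graphlet counts match closed forms on canonical graphs", {
  for (n in c(4, 6, 9)) {
    kn <- count_graphlets(psn_from_adjacency(1 - diag(n)))$counts
    expect_identical(unname(kn["edge"]), choose(n, 2))
    expect_identical(unname(kn["triangle"]), choose(n, 3))
    expect_identical(unname(kn["four_clique"]), choose(n, 4))
    expect_identical(unname(kn["two_path"]), 0)
    # star S_n: hub + n leaves
    a <- matrix(0, n + 1, n + 1)
    a[1, 2:(n + 1)] <- a[2:(n + 1), 1] <- 1
    st <- count_graphlets(psn_from_adjacency(a))$counts
    expect_identical(unname(st["two_path"]), choose(n, 2))
    expect_identical(unname(st["three_star"]), choose(n, 3))
    expect_identical(unname(st["triangle"]), 0)
    # path P_n
    a <- matrix(0, n, n)
    for (i in seq_len(n - 1)) a[i, i + 1] <- a[i + 1, i] <- 1
    pn <- count_graphlets(psn_from_adjacency(a))$counts
    expect_identical(unname(pn["edge"]), n - 1)
    expect_identical(unname(pn["two_path"]), n - 2)
    expect_identical(unname(pn["three_path"]), n - 3)
    expect_identical(sum(pn[c("triangle", "three_star", "four_cycle",
                              "tailed_triangle", "diamond",
                              "four_clique")]), 0)
  }
})

test_that("graphlet counts equal exhaustive subset enumeration on random graphs", {
  withr::with_seed(99, {
    for (i in 1:60) {
      n <- sample(4:12, 1)
      a <- random_adjacency(n, stats::runif(1, 0.15, 0.7))
      expect_identical(count_graphlets(psn_from_adjacency(a))$counts,
                       brute_graphlets(a))
    }
  })
})

test_that("graphlet counts agree with an igraph motif census", {
  skip_if_not_installed("igraph")
  withr::with_seed(123, {
    for (i in 1:10) {
      a <- random_adjacency(10, 0.4)
      g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
      ours <- count_graphlets(psn_from_adjacency(a))$counts
      m3 <- igraph::motifs(g, 3)
      expect_equal(unname(ours["two_path"]), m3[3])
      expect_equal(unname(ours["triangle"]), m3[4])
      m4 <- igraph::motifs(g, 4)
      # igraph size-4 undirected census positions: 5=three_star,
      # 7=three_path, 8=tailed_triangle, 9=four_cycle, 10=diamond,
      # 11=four_clique
      expect_equal(unname(ours[c("three_star", "three_path",
                                 "tailed_triangle", "four_cycle", "diamond",
                                 "four_clique")]),
                   unname(m4[c(5, 7, 8, 9, 10, 11)]))
    }
  })
})

test_that("graphlet counts are isomorphism-invariant", {
  withr::with_seed(55, {
    for (i in 1:10) {
      a <- random_adjacency(10, 0.4)
      perm <- sample(10)
      expect_identical(count_graphlets(psn_from_adjacency(a))$counts,
                       count_graphlets(psn_from_adjacency(a[perm, perm]))$counts)
    }
  })
})

test_that("static and dynamic features have the documented shape and semantics", {
  native <- make_helix(12, protein_id = "f")
  dp <- build_dynamic_psn(generate_proxy_intermediates(native, 5))
  sf <- static_features(dp$snapshots[[3]])
  expect_length(sf, 9)
  expect_equal(sum(sf), 1, tolerance = 1e-12)
  # single-snapshot reduction
  one <- build_dynamic_psn(generate_proxy_intermediates(native, 12))
  df1 <- dynamic_features(one, n_bins = 1)
  expect_length(df1, 18)
  expect_equal(unname(df1[1:9]), unname(static_features(one$snapshots[[1]])))
  # identical snapshots repeated -> every bin equals the static vector
  rep_pw <- new_pathway(lapply(1:3, function(t) {
    nascentfold:::conf_prefix(native, 12, intermediate_index = t)
  }), validate = FALSE)
  dfr <- dynamic_features(build_dynamic_psn(rep_pw), n_bins = 3)
  for (b in 1:3) {
    expect_equal(unname(dfr[(b - 1) * 9 + 1:9]),
                 unname(static_features(one$snapshots[[1]])))
  }
  # arrival: triangles first appearing at snapshot 3 of 4 -> 0.75
  line <- collinear_conf(3.8, 12)
  tri_pw <- new_pathway(list(
    nascentfold:::conf_prefix(line, 4, intermediate_index = 1),
    nascentfold:::conf_prefix(line, 8, intermediate_index = 2),
    make_helix(10, protein_id = "line") |>
      (\(h) {
        attr(h, "intermediate_index") <- 3L
        h
      })(),
    (\(h) {
      attr(h, "intermediate_index") <- 4L
      h
    })(make_helix(12, protein_id = "line"))
  ), validate = FALSE)
  dft <- dynamic_features(build_dynamic_psn(tri_pw), n_bins = 4)
  expect_equal(unname(dft["triangle_arrival"]), 0.75)
  expect_equal(unname(dft["edge_arrival"]), 0.25)
  # zero-graphlet snapshot yields an all-zero frequency vector
  lonely <- build_psn(collinear_conf(20, 3))
  expect_identical(unname(static_features(lonely)), rep(0, 9))
})
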