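test_that("curation drops flagged conformations and counts what remains", {
  m <- read_manifest(cotranslational_catalogue())
  cu <- curate_manifest(m)
  expect_identical(cu$summary$n_conformations_catalogued, 17L)
  expect_identical(cu$summary$n_conformations_retained, 15L)
  expect_identical(cu$summary$n_intermediates_retained, 10L)
  expect_false(any(cu$retained$excluded))
  # no exclusions -> identity
  cu2 <- curate_manifest(cu$retained)
  expect_identical(nrow(cu2$retained), nrow(cu$retained))
  # all excluded -> warning, zero retained
  allx <- dplyr::mutate(m, excluded = TRUE,
                        exclusion_reason = "synthetic test exclusion")
  expect_warning(cu3 <- curate_manifest(allx), "all")
  expect_identical(nrow(cu3$retained), 0L)
})

test_that("same-intermediate comparisons score all unordered pairs", {
  base <- make_coil(30, seed = 41, protein_id = "si")
  copies <- lapply(1:3, function(i) {
    attr(base, "conformation_label") <- letters[i]
    base
  })
  rec <- compare_same_intermediate(copies)
  expect_identical(nrow(rec), 3L)
  expect_true(all(abs(rec$tm - 1) < 1e-9))
  expect_true(all(rec$band == "same_fold"))
  # a rigid-moved copy still matches exactly
  withr::with_seed(8, {
    moved <- random_rigid_motion(copies[[2]])
    rec2 <- compare_same_intermediate(list(copies[[1]], moved))
    expect_equal(rec2$tm, 1, tolerance = 1e-6)
  })
  # genuinely different conformations of one intermediate: changed folds
  hinged <- lapply(c(0, 120, 240), function(a) {
    h <- make_hinged(base, 15, a)
    h
  })
  rec3 <- compare_same_intermediate(hinged)
  expect_true(all(rec3$tm <= 1))
  bad <- base
  attr(bad, "intermediate_index") <- 5L
  expect_error(compare_same_intermediate(list(base, bad)),
               "intermediate_index")
})

test_that("across-time comparisons map the earlier subsequence and label distance", {
  native <- make_coil(40, seed = 51, protein_id = "at")
  proxies <- generate_proxy_intermediates(native, 10)
  rec <- compare_across_time(proxies, "all")
  # proxy pathways share coordinates: every record is an exact match
  expect_true(all(abs(rec$tm - 1) < 1e-9))
  expect_identical(sum(rec$mode == "across_time_consecutive"), 3L)
  expect_identical(sum(rec$mode == "across_time_distant"), 3L)
  two <- new_pathway(list(
    nascentfold:::conf_prefix(native, 10, intermediate_index = 1),
    nascentfold:::conf_prefix(native, 20, intermediate_index = 2)
  ), validate = FALSE)
  expect_identical(nrow(compare_across_time(two)), 1L)
  # hinge-perturbed pathways diverge more at larger time distance
  mean_by_mode <- function(hinge, seed) {
    r <- compare_across_time(
      simulate_cotranslational_pathway(native, 10, hinge, seed = seed),
      "all")
    tapply(r$tm, r$mode, mean)
  }
  withr::with_seed(6, {
    ms <- sapply(1:20, function(s) mean_by_mode(25, s))
    expect_gt(mean(ms["across_time_consecutive", ]),
              mean(ms["across_time_distant", ]))
  })
})

test_that("prediction evaluation matches by identity and reports gaps", {
  exps <- lapply(1:3, function(i) {
    c <- make_coil(20 + i, seed = 60 + i, protein_id = "pv")
    attr(c, "intermediate_index") <- i
    c
  })
  # predictions = the experimental files -> perfect scores
  res <- evaluate_predictions(exps, exps)
  expect_identical(nrow(res$records), 3L)
  expect_true(all(abs(res$records$tm - 1) < 1e-9))
  expect_identical(nrow(res$gaps), 0L)
  # one missing prediction -> gap entry, not an error
  res2 <- evaluate_predictions(exps, exps[1:2])
  expect_identical(nrow(res2$records), 2L)
  expect_identical(nrow(res2$gaps), 1L)
  # rank handling: score the top-ranked prediction only
  p1 <- exps[[1]]
  attr(p1, "prediction_rank") <- 2L
  res3 <- evaluate_predictions(exps[1], list(p1))
  expect_identical(nrow(res3$records), 0L)
  expect_identical(nrow(res3$gaps), 1L)
})

test_that("random-coil decoys of helical targets score below the fold threshold", {
  withr::with_seed(14, {
    tms <- sapply(1:20, function(s) {
      target <- make_helix(50, protein_id = "decoy")
      attr(target, "intermediate_index") <- 1L
      decoy <- make_coil(50, seed = 700 + s, protein_id = "decoy")
      attr(decoy, "intermediate_index") <- 1L
      evaluate_predictions(list(target), list(decoy))$records$tm
    })
    expect_lt(mean(tms), 0.5)
  })
})

test_that("proxy evaluation matches lengths and is exact on self-matches", {
  native <- make_coil(60, seed = 71, protein_id = "pe")
  # the native itself -> matched to the full-length proxy, TM = 1
  rec <- evaluate_proxies(native, 5, list(native))
  expect_identical(rec$mode, "proxy_vs_experiment")
  expect_equal(rec$tm, 1, tolerance = 1e-9)
  # the proxies themselves -> all exact
  pw <- generate_proxy_intermediates(native, 5)
  rec2 <- evaluate_proxies(native, 5, pw$conformation)
  expect_true(all(abs(rec2$tm - 1) < 1e-9))
  # hinge-perturbed prefixes drift away monotonically on average
  pre <- nascentfold:::conf_prefix(native, 30)
  tms <- sapply(c(30, 90, 150), function(a) {
    evaluate_proxies(native, 5, list(make_hinged(pre, 15, a)))$tm
  })
  expect_true(all(diff(tms) < 0))
  # an experimental conformation longer than the native is skipped
  long <- make_coil(70, seed = 72, protein_id = "pe")
  rec3 <- evaluate_proxies(native, 5, list(long))
  expect_identical(nrow(rec3), 0L)
  expect_identical(nrow(attr(rec3, "skipped")), 1L)
})

test_that("contact order averages the sequence separation of contacts", {
  # constructed contact set {(1,5), (2,8)} -> absolute CO = 5
  res <- tibble::tibble(
    seq_index = 1:8, aa = "A",
    x = c(0, 50, 100, 150, 3, 200, 250, 53),
    y = c(0, 0, 0, 0, 0, 0, 0, 0),
    z = 0
  )
  conf <- new_conformation(res, "co")
  co <- contact_order(conf, cutoff = 6, min_sequence_separation = 2)
  expect_identical(co$n_contacts, 2L)
  expect_equal(co$absolute_co, 5)
  expect_equal(co$relative_co, 5 / 8)
  # ideal extended strand: no contacts at separation >= 2
  co2 <- contact_order(make_strand(30), cutoff = 6,
                       min_sequence_separation = 2)
  expect_identical(co2$n_contacts, 0L)
  expect_true(is.na(co2$absolute_co))
  # helix contact order at separation >= 2 lies in [2, 4]
  co3 <- contact_order(make_helix(40))
  expect_gte(co3$absolute_co, 2)
  expect_lte(co3$absolute_co, 4)
})

test_that("two-state fraction reflects the mix of concerted and sequential pathways", {
  l <- 30
  sse <- tibble::tibble(label = c("A", "B", "C"),
                        start = c(1, 11, 21), end = c(10, 20, 30))
  native <- make_helix(l, protein_id = "ts")
  two_state <- function() {
    new_pathway(list(extended_chain(l, 1),
                     partial_helix(l, l, 2),
                     partial_helix(l, l, 3),
                     partial_helix(l, l, 4)), validate = FALSE)
  }
  sequential <- function() {
    new_pathway(list(extended_chain(l, 1),
                     partial_helix(20, l, 2),
                     partial_helix(20, l, 3),
                     partial_helix(l, l, 4)), validate = FALSE)
  }
  pws <- c(replicate(5, two_state(), simplify = FALSE),
           replicate(5, sequential(), simplify = FALSE))
  rep <- suppressWarnings(
    two_state_stats(pws, native, sse, window = 1))
  expect_equal(rep$two_state_fraction, 0.5)
  expect_identical(sum(rep$pathway_summary$is_two_state), 5L)
  # order invariance and duplication stability
  rep2 <- suppressWarnings(two_state_stats(rev(pws), native, sse))
  expect_equal(rep2$two_state_fraction, 0.5)
  rep3 <- suppressWarnings(two_state_stats(c(pws, pws), native, sse))
  expect_equal(rep3$two_state_fraction, 0.5)
  # all contacts first complete in the final snapshot -> fraction 1
  rep4 <- suppressWarnings(two_state_stats(
    list(new_pathway(list(extended_chain(l, 1), extended_chain(l, 2),
                          partial_helix(l, l, 3)), validate = FALSE)),
    native, sse))
  expect_equal(rep4$two_state_fraction, 1)
  # degenerate single informative SSE pair -> warning + trivially two-state
  sse2 <- tibble::tibble(label = c("A", "B"), start = c(1, 11),
                         end = c(10, 20))
  expect_warning(rep5 <- two_state_stats(list(two_state()), native, sse2),
                 "degenerate")
  expect_equal(rep5$two_state_fraction, 1)
  expect_identical(nrow(glance(rep5)), 1L)
})
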