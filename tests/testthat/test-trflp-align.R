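toy_profile <- function(sizes, areas, heights, sample_id = "S1") {
  tibble::tibble(
    sample_id = sample_id, gene = "nirK", enzyme = "HaeIII",
    size_bp = sizes, area = areas, height = heights
  )
}

test_that("shoulder peaks merge by the closest-pair rule", {
  p <- toy_profile(c(100.0, 100.3), c(10, 2), c(8, 1))
  m <- smooth_peaks(p)
  expect_equal(nrow(m), 1)
  expect_equal(m$size_bp, 100.05) # area-weighted mean
  expect_equal(m$area, 12)
  expect_equal(m$height, 8)

  # peaks at or beyond the merge window are untouched
  q <- toy_profile(c(100.0, 100.5, 103), c(1, 2, 3), c(1, 2, 3))
  expect_equal(smooth_peaks(q)$size_bp, q$size_bp)
})

test_that("chain merging proceeds closest-pair-first (leftmost on ties)", {
  # gaps 0.25 and 0.25 (exact ties in binary): the leftmost pair merges
  # first into (100.041667, a=12); the survivor then sits 0.4583 bp from
  # the third peak, still inside the window, so the chain collapses to
  # one peak whose position is the iterated area-weighted mean
  p <- toy_profile(c(100.0, 100.25, 100.5), c(10, 2, 4), c(8, 1, 3))
  m <- smooth_peaks(p)
  step1 <- (10 * 100.0 + 2 * 100.25) / 12
  expect_equal(nrow(m), 1)
  expect_equal(m$size_bp, (12 * step1 + 4 * 100.5) / 16, tolerance = 1e-12)
  expect_equal(m$area, 16)
  expect_equal(m$height, 8)
})

test_that("relativization normalizes areas and heights and is idempotent", {
  p <- toy_profile(c(100, 120, 140), c(2, 3, 5), c(1, 1, 2))
  r <- relativize_peaks(p)
  expect_equal(r$area, c(0.2, 0.3, 0.5))
  expect_equal(sum(r$height), 1)
  expect_equal(relativize_peaks(r), r)
  single <- relativize_peaks(toy_profile(100, 7, 3))
  expect_equal(single$area, 1)
  expect_equal(single$height, 1)
  expect_error(relativize_peaks(toy_profile(c(100, 110), c(0, 0), c(0, 0))), "all-zero")
})

test_that("iterative baseline classification separates signal from noise", {
  # 2 real peaks among 200 tiny ones: first pass sigma ~ 0.029 flags both
  # large peaks; second pass sigma = 0.002 flags nothing more
  areas <- c(0.30, 0.28, rep(0.002, 200))
  p <- toy_profile(seq(100, by = 1, length.out = 202), areas, areas)
  cl <- classify_peaks(p)
  expect_equal(sum(cl$peak_class == "signal"), 2)
  expect_equal(cl$peak_class[1:2], c("signal", "signal"))

  # identical peaks can never exceed 3x their own RMS baseline
  u <- toy_profile(seq(100, 109), rep(0.1, 10), rep(0.1, 10))
  expect_true(all(classify_peaks(u)$peak_class == "noise"))

  # classification is invariant to row order
  perm <- withr::with_seed(1, p[sample(nrow(p)), ])
  cl2 <- classify_peaks(perm)
  expect_equal(
    cl2$peak_class[order(cl2$size_bp)],
    cl$peak_class[order(cl$size_bp)]
  )
})

test_that("the OR noise rule admits peaks large in either dimension", {
  p <- toy_profile(c(100, 105, 110), c(0.6, 0.01, 0.39), c(0.05, 0.6, 0.35))
  and_cl <- classify_peaks(p, align_params(noise_rule = "and"))$peak_class
  or_cl <- classify_peaks(p, align_params(noise_rule = "or"))$peak_class
  expect_true(sum(or_cl == "signal") >= sum(and_cl == "signal"))
})

test_that("peak dissimilarity combines weighted differences with a drift cutoff", {
  expect_equal(peak_dissimilarity(100, 0.2, 0.1, 100, 0.2, 0.1), 0)
  expect_equal(peak_dissimilarity(100.0, 0.2, 0.1, 100.4, 0.25, 0.12), 0.47)
  expect_equal(peak_dissimilarity(100, 0.2, 0.1, 101.01, 0.2, 0.1), Inf)
  half <- align_params(w_size = 0.5, w_area = 2, w_height = 0.1)
  expect_equal(peak_dissimilarity(100.0, 0.2, 0.1, 100.4, 0.25, 0.9, half), 0.38)
})

test_that("pairwise DP alignment is exact against brute-force enumeration", {
  params <- align_params()
  p <- random_toy_profile(3)
  expect_equal(align_pair(p, p, params)$cost, 0)
  expect_equal(nrow(align_pair(p, p, params)$pairs), 3)

  # disjoint size ranges: everything gapped
  q <- dplyr::mutate(p, size_bp = size_bp + 50)
  pa <- align_pair(p, q, params)
  expect_equal(nrow(pa$pairs), 0)
  expect_equal(pa$cost, params$gap_cost * 6)

  withr::with_seed(33, {
    for (rep in 1:40) {
      a <- random_toy_profile(sample(1:5, 1))
      b <- random_toy_profile(sample(1:5, 1))
      got <- align_pair(a, b, params)
      expect_equal(got$cost, oracle_pair_cost(a, b, params), tolerance = 1e-12)
      # reported decomposition is consistent
      expect_equal(
        got$cost,
        sum(got$pairs$cost) + params$gap_cost * (length(got$unmatched_p) + length(got$unmatched_q))
      )
    }
  })
  expect_error(align_pair(p[c(2, 1, 3), ], p, params), "sorted")
})

test_that("identical profiles align into zero-score full-occupancy bins", {
  base <- relativize_peaks(toy_profile(c(100, 150, 200), c(1, 2, 3), c(3, 2, 1)))
  peaks <- dplyr::bind_rows(lapply(sprintf("S%d", 1:5), function(s) {
    dplyr::mutate(base, sample_id = s)
  }))
  aln <- align_profiles(peaks, seed = 7)
  expect_equal(nrow(aln$bins), 3)
  expect_equal(aln$bins$occupancy, rep(5L, 3))
  expect_equal(aln$score, 0)
  expect_equal(sort(aln$bins$consensus_size), sort(base$size_bp))
  # refinement cannot improve a perfect alignment
  ref <- refine_alignment(aln, seed = 2)
  expect_equal(ref$score, 0)
  expect_equal(ref$bins, aln$bins)
  expect_error(align_profiles(dplyr::filter(peaks, sample_id == "S1")), "2 samples")
})

test_that("alignments are deterministic under a fixed seed", {
  peaks <- sim_trflp_profiles(trflp_truth(), n_samples = 8, seed = 4) |>
    smooth_peaks() |>
    relativize_peaks() |>
    classify_peaks()
  a1 <- align_profiles(peaks, seed = 5)
  a2 <- align_profiles(peaks, seed = 5)
  expect_equal(a1$bins, a2$bins)
  expect_equal(a1$score, a2$score)
  expect_identical(
    refine_alignment(a1, seed = 9)$members,
    refine_alignment(a2, seed = 9)$members
  )
})

test_that("alignment invariants hold on synthetic data", {
  peaks <- sim_trflp_profiles(trflp_truth(), n_samples = 10, seed = 14)
  res <- align_trflp(peaks, seed = 2)
  aln <- res$alignments[[1]]
  # one peak per sample per bin
  per <- dplyr::count(aln$members, bin_id, sample_id)
  expect_true(all(per$n == 1))
  # strictly increasing consensus sizes
  expect_true(all(diff(aln$bins$consensus_size) > 0))
  # stored score equals the recomputed score
  expect_equal(aln$score, alignment_score(aln), tolerance = 1e-9)
})

test_that("leave-one-out refinement never worsens the accepted score", {
  peaks <- sim_trflp_profiles(trflp_truth(), n_samples = 6, seed = 20) |>
    smooth_peaks() |>
    relativize_peaks() |>
    classify_peaks()

  ok <- 0
  for (s in 1:15) {
    aln <- align_profiles(peaks, seed = s)
    ref <- refine_alignment(aln, seed = s + 100)
    expect_lte(ref$score, aln$score)
    expect_true(all(diff(ref$score_history) < 0)) # accepted passes strictly improve
    if (bin_purity(ref) >= bin_purity(aln)) ok <- ok + 1
  }
  expect_gte(ok / 15, 0.9)
})

test_that("two-enzyme combination concatenates bin matrices faithfully", {
  truth_a <- trflp_truth(default_fragment_panel(12, enzyme = "HaeIII"))
  truth_b <- trflp_truth(default_fragment_panel(9, enzyme = "HpyCH4IV", size_range = c(70, 430)))
  mk <- function(truth) {
    sim_trflp_profiles(truth, n_samples = 5, seed = 3) |>
      relativize_peaks() |>
      classify_peaks() |>
      align_profiles(seed = 1)
  }
  a <- mk(truth_a)
  b <- mk(truth_b)
  comb <- combine_enzymes(a, b)
  ma <- as_bin_matrix(a)
  mb <- as_bin_matrix(b)
  expect_equal(ncol(comb) - 1, (ncol(ma) - 1) + (ncol(mb) - 1))
  expect_equal(comb$sample_id, ma$sample_id)
  expect_equal(
    rowSums(comb[, -1]),
    rowSums(ma[, -1]) + rowSums(mb[, -1])
  )
  # enzyme prefixes keep bin ids distinct
  expect_true(all(grepl("^(HaeIII|HpyCH4IV)_", names(comb)[-1])))

  b_dropped <- b
  b_dropped$samples <- b_dropped$samples[-1]
  b_dropped$members <- dplyr::filter(b_dropped$members, sample_id != "S01")
  expect_error(combine_enzymes(a, b_dropped), "same samples")
})
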