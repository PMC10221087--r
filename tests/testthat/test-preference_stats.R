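test_that("within-row ranking averages ties and validates input", {
  m <- rbind(F = c(A = 0.9, C = 0.1, G = 0.1, U = 0.1))
  expect_equal(unname(rank_rows(m)[1, ]), c(1, 3, 3, 3))
  m2 <- rbind(X = c(A = 4, C = 3, G = 2, U = 1))
  expect_equal(unname(rank_rows(m2)[1, ]), 1:4)
  set.seed(3)
  m3 <- matrix(runif(40), 10, 4,
               dimnames = list(letters[1:10], c("A", "C", "G", "U")))
  expect_true(all(rowSums(rank_rows(m3)) == 10))
  m3[2, 3] <- NA
  expect_error(rank_rows(m3), "missing entries")
})

test_that("exact binomial tails match published and brute-force values", {
  expect_equal(binomial_preference_test(10, 20, 0.25, "upper"), 0.0139,
               tolerance = 5e-3)
  expect_equal(binomial_preference_test(2, 23, 0.25, "lower"), 0.0492,
               tolerance = 5e-3)
  expect_equal(binomial_preference_test(19, 20, 0.75, "upper"), 0.0243,
               tolerance = 5e-3)
  expect_equal(binomial_preference_test(0, 15, 0.25, "upper"), 1)
  # brute-force enumeration of all 4^n outcomes, n <= 8
  for (n in c(4, 6, 8)) for (k in c(0, 1, n %/% 2, n)) {
    expect_equal(binomial_preference_test(k, n, 0.25, "upper"),
                 brute_binom_tail(k, n, "upper"), tolerance = 1e-12)
    expect_equal(binomial_preference_test(k, n, 0.25, "lower"),
                 brute_binom_tail(k, n, "lower"), tolerance = 1e-12)
  }
  expect_error(binomial_preference_test(5, 3, 0.25), "k <= n")
})

test_that("first-choice summary counts strict cognate bests", {
  alloc <- expand_assignments(position = "anticodon2")
  aas <- unique(alloc$amino_acid)
  # plant every amino acid's cognate anticodon middle base as the strict
  # best binder
  best <- vapply(aas, function(aa)
    alloc$cognate[[match(aa, alloc$amino_acid)]][1], "")
  m <- toy_matrix(best, seed = 2)
  ranks <- rank_rows(m)
  fc <- first_choice_summary(ranks, alloc)
  # Ser's second family has a different middle base, so at most 22 of
  # the 23 allocations can be cognate-first simultaneously
  expect_equal(fc$n_cognate_first, 22)
  expect_equal(fc$n_best_any_cognate, 20)
  # all-tied matrix: no strict first choices
  flat <- matrix(1, length(aas), 4,
                 dimnames = list(aas, c("A", "C", "G", "U")))
  fc0 <- first_choice_summary(rank_rows(flat), alloc)
  expect_equal(fc0$n_cognate_first, 0)
  expect_equal(fc0$n_cognate_last, 0)
})

test_that("random matrices put the cognate first about a quarter of the time", {
  alloc <- expand_assignments(position = "anticodon2")
  aas <- unique(alloc$amino_acid)
  set.seed(10)
  n_draw <- 2000
  counts <- vapply(seq_len(n_draw), function(i) {
    m <- matrix(runif(20 * 4), 20, 4,
                dimnames = list(aas, c("A", "C", "G", "U")))
    first_choice_summary(rank_rows(m), alloc)$n_cognate_first
  }, 0)
  # mean cognate-first count under the uniform null ~ n_allocations / 4
  se <- sd(counts) / sqrt(n_draw)
  expect_lt(abs(mean(counts) - 23 / 4), 4 * se)
})

test_that("sum-of-ranks score spans the documented bounds", {
  alloc20 <- expand_assignments(position = "anticodon2")
  aas <- unique(alloc20$amino_acid)
  best <- vapply(aas, function(aa)
    alloc20$cognate[[match(aa, alloc20$amino_acid)]][1], "")
  # single allocation per amino acid: best case 20, worst case 80
  alloc_single <- alloc20[!duplicated(alloc20$amino_acid), ]
  ranks_best <- rank_rows(toy_matrix(best, seed = 4))
  expect_equal(rank_sum_score(ranks_best, alloc_single), 20)
  worst_m <- toy_matrix(best, seed = 5)
  # invert so the cognate is strictly worst
  worst_m <- max(worst_m) + 1 - worst_m
  expect_equal(rank_sum_score(rank_rows(worst_m), alloc_single), 80)
  # hexacodonic expansion raises the minimum to 23 (Ser's second family
  # cannot simultaneously be first, so the floor uses the best rank per
  # allocation; verify on an all-first construction per allocation)
  expect_gte(rank_sum_score(ranks_best, alloc20), 23)
  ranks_worst <- rank_rows(worst_m)
  expect_lte(rank_sum_score(ranks_worst, alloc20), 92)
})

test_that("randomization null is calibrated and deterministic", {
  alloc <- expand_assignments(position = "anticodon2")
  rs <- randomization_null(40, alloc, n_columns = 4,
                           n_randomizations = 20000, seed = 1)
  # uniform rank expectation: 2.5 per allocation
  se <- sd(rs$null_sums) / sqrt(length(rs$null_sums))
  expect_lt(abs(rs$null_mean - 2.5 * 23), 4 * se)
  expect_true(all(rs$null_sums >= 23 & rs$null_sums <= 92))
  # minimum possible observed score beats every non-degenerate draw
  rs_min <- randomization_null(23, alloc, n_randomizations = 5000,
                               seed = 2)
  expect_gte(rs_min$frac_stronger, 1 - mean(rs_min$null_sums == 23) - 1e-9)
  # determinism
  rs2 <- randomization_null(40, alloc, n_columns = 4,
                            n_randomizations = 20000, seed = 1)
  expect_identical(rs$null_sums, rs2$null_sums)
})

test_that("the dinucleotide constraint forbids identical cognate ranks", {
  tab <- standard_code_table()
  # dinucleotide scheme: 16 columns; Ser, Arg, Leu each have two cognate
  # dinucleotide allocations
  alloc <- expand_assignments(tab, position = "codon2")
  expect_warning(randomization_null(50, alloc, n_columns = 4,
                                    n_randomizations = 10, seed = 1,
                                    dinucleotide_constraint = TRUE),
                 "ignored")
  rs <- randomization_null(50, alloc, n_columns = 16,
                           n_randomizations = 3000, seed = 3,
                           dinucleotide_constraint = TRUE)
  # reconstruct the per-draw equality check from the stored settings by
  # re-running with the same seed and inspecting group sums cannot be
  # done without the draws, so check the distributional signature:
  # constrained draws exclude equal pairs, shifting no mass outside
  # bounds
  expect_true(all(rs$null_sums >= nrow(alloc)))
  expect_true(all(rs$null_sums <= 16 * nrow(alloc)))
  # direct check on a minimal two-allocation table over 16 dinucleotide
  # columns: ranks sampled without replacement within the amino acid
  toy <- expand_assignments(position = "codon2")
  toy <- toy[toy$amino_acid == "S", ]
  rs2 <- randomization_null(2, toy, n_columns = 16,
                            n_randomizations = 20000, seed = 5,
                            dinucleotide_constraint = TRUE)
  # sums achievable only via identical ranks never occur
  expect_equal(sum(rs2$null_sums == 2), 0)    # (1, 1)
  expect_equal(sum(rs2$null_sums == 32), 0)   # (16, 16)
  # P(sum = 3) = P{(1,2) or (2,1)} = 2 / (16 * 15)
  expect_lt(abs(mean(rs2$null_sums == 3) - 2 / 240), 0.005)
  # unconstrained draws do produce identical ranks
  rs3 <- randomization_null(2, toy, n_columns = 16,
                            n_randomizations = 20000, seed = 5)
  expect_gt(sum(rs3$null_sums == 2), 0)
})

test_that("directionality comparison is antisymmetric and detects shifts", {
  xy <- gen_distance_series(0.4, n_runs = 30, n_frames = 400, seed = 11)
  yx <- gen_distance_series(0.2, n_runs = 30, n_frames = 400, seed = 12)
  cmp <- directionality_compare(xy, yx, n_boot = 2000, seed = 1)
  expect_gt(cmp$difference, 0)
  expect_true(cmp$excludes_zero)
  rev <- directionality_compare(yx, xy, n_boot = 2000, seed = 1)
  expect_equal(rev$difference, -cmp$difference)
  # identical series: difference 0, interval spans it
  same <- directionality_compare(xy, xy, n_boot = 2000, seed = 2)
  expect_equal(same$difference, 0)
  expect_lte(same$ci95[1], 0)
  expect_gte(same$ci95[2], 0)
  expect_error(directionality_compare(xy, NULL), "both orientations")
})
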