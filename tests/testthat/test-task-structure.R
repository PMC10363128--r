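test_that("pattern construction validates and induces the right transitions", {
  p <- asrt_pattern(c(1, 2, 4, 3))
  pairs <- pattern_transitions(p)
  expect_setequal(paste(pairs[, 1], pairs[, 2]),
                  c("1 2", "2 4", "4 3", "3 1"))
  p_id <- asrt_pattern(1:4)
  expect_setequal(paste(p_id$pairs[, 1], p_id$pairs[, 2]),
                  c("1 2", "2 3", "3 4", "4 1"))
  expect_error(asrt_pattern(c(1, 1, 2, 3)), "permutation")
  expect_error(asrt_pattern(c(1, 2, 3)), "permutation")
  expect_identical(asrt_pattern(seed = 7)$order, asrt_pattern(seed = 7)$order)
  # no self-transitions in any cycle
  for (q in all_patterns()) expect_true(all(q$pairs[, 1] != q$pairs[, 2]))
})

test_that("triplet census is 16 high / 48 low for every one of the 24 cycles", {
  pats <- all_patterns()
  expect_length(pats, 24L)
  for (p in pats) {
    cen <- triplet_census(p)
    expect_identical(unname(cen[c("high", "low", "total")]), c(16L, 48L, 64L))
    tr <- enumerate_triplets(p)
    # trills/repetitions: 16 of them, all low-probability
    expect_identical(sum(tr$trill_or_rep), 16L)
    expect_false(any(tr$high & tr$trill_or_rep))
    expect_false(any(tr$high & tr$first == tr$middle & tr$middle == tr$third))
  }
})

test_that("analytic occurrence probabilities are the exact task fractions", {
  for (p in all_patterns()[c(1, 9, 24)]) {
    occ <- analytic_occurrence(p)
    expect_identical(occ$overall_high, 0.625)
    expect_identical(occ$overall_low, 0.375)
    expect_identical(occ$pattern_ending_high_share, 0.5)
    expect_identical(occ$random_ending_high_share, 0.125)
    expect_identical(occ$per_unique_high, 0.625 / 16)
    expect_identical(occ$per_unique_low, 0.375 / 48)
    # partitions are coherent
    expect_equal(occ$overall_high + occ$overall_low, 1)
    expect_equal(occ$pattern_ending_high_share + occ$random_ending_high_share,
                 occ$overall_high)
    expect_equal(16 * occ$per_unique_high + 48 * occ$per_unique_low, 1)
  }
})

test_that("generated sessions have the alternating block structure", {
  p <- asrt_pattern(c(1, 2, 4, 3))
  s <- generate_session(p, n_blocks = 40, seed = 11)
  expect_identical(nrow(s), 3400L)
  expect_identical(sum(s$origin == "pattern"), 1600L)
  expect_identical(sum(s$origin %in% c("random", "warmup")), 1800L)
  expect_identical(sum(s$origin == "warmup"), 200L)
  # pattern trials sit at indices 6, 8, ..., 84 and cycle the order,
  # restarting every block
  for (b in c(1L, 17L)) {
    blk <- s[s$block == b, ]
    expect_identical(blk$index_in_block[blk$origin == "pattern"],
                     seq(6L, 84L, by = 2L))
    expect_identical(blk$position[blk$origin == "pattern"],
                     rep(p$order, 10L))
  }
  expect_identical(generate_session(p, 3, seed = 5),
                   generate_session(p, 3, seed = 5))
  expect_error(generate_session(p, 0), "n_blocks")
})

test_that("practice blocks are pattern-free with uniform positions", {
  pr <- generate_practice_blocks(2, seed = 3)
  expect_identical(nrow(pr), 170L)
  expect_false(any(pr$origin == "pattern"))
  expect_identical(nrow(generate_practice_blocks(0)), 0L)
  # chi-square uniformity over a large sample
  big <- generate_practice_blocks(1200, seed = 42)  # 102000 trials
  ct <- table(big$position)
  expect_gt(stats::chisq.test(ct)$p.value, 0.01)
})

test_that("empirical triplet frequencies match the analytic probabilities", {
  p <- asrt_pattern(c(2, 4, 1, 3))
  s <- generate_session(p, n_blocks = 1177, seed = 99)  # ~1e5 trials
  cl <- classify_triplets(s, pattern = p)
  classifiable <- cl$triplet_class %in% c("HIGH", "LOW", "TRILL_OR_REP")
  # trills/repetitions count as LOW for the occurrence split
  is_high <- cl$triplet_class[classifiable] == "HIGH"
  n <- sum(classifiable)
  occ <- analytic_occurrence(p)
  tol3se <- function(p0) 3 * sqrt(p0 * (1 - p0) / n)
  expect_lt(abs(mean(is_high) - occ$overall_high), tol3se(occ$overall_high))
  pat_high <- cl$origin[classifiable] == "pattern" & is_high
  expect_lt(abs(mean(pat_high) - occ$pattern_ending_high_share),
            tol3se(occ$pattern_ending_high_share))
  rnd_high <- cl$origin[classifiable] == "random" & is_high
  expect_lt(abs(mean(rnd_high) - occ$random_ending_high_share),
            tol3se(occ$random_ending_high_share))
  # pattern-ending classifiable trials are high-probability with certainty
  expect_true(all(is_high[cl$origin[classifiable] == "pattern"]))
})
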