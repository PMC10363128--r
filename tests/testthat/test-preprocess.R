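test_that("sliding-window classification reproduces worked examples", {
  p <- asrt_pattern(c(1, 2, 4, 3))  # transitions 1->2, 2->4, 4->3, 3->1
  # stream at indices 6..13: 1 3 2 1 4 2 3 2 (warm-ups all at position 4)
  tr <- manual_block(c(1, 3, 2, 1, 4, 2, 3, 2))
  cl <- classify_triplets(tr, pattern = p)
  expect_identical(cl$triplet_class[1:5], rep("UNCLASSIFIABLE", 5L))
  expect_identical(cl$exclusion_reason[1:5], rep("warmup", 5L))
  # trials 6 and 7 lack two post-warm-up predecessors
  expect_identical(cl$exclusion_reason[6:7], rep("no_window", 2L))
  # windows then advance one trial at a time: trial 8 ends (1,3,2) -> HIGH,
  # trial 9 ends (3,2,1) -> HIGH, then (2,1,4), (1,4,2), (4,2,3) all HIGH,
  # and trial 13 ends the trill (2,3,2)
  expect_identical(cl$triplet_class[8:13],
                   c("HIGH", "HIGH", "HIGH", "HIGH", "HIGH", "TRILL_OR_REP"))
})

test_that("trills and repetitions are flagged and would otherwise be low", {
  p <- asrt_pattern(c(1, 2, 4, 3))
  tr <- manual_block(c(2, 1, 2, 2, 2))  # 2-1-2 trill, then 2-2-2 repetition
  cl <- classify_triplets(tr, pattern = p)
  expect_identical(cl$triplet_class[c(8L, 10L)],
                   c("TRILL_OR_REP", "TRILL_OR_REP"))
  expect_identical(cl$exclusion_reason[8], "trill_or_rep")
  # cross-check: a trill endpoint is never the pattern successor of its
  # two-back element, so the label only ever displaces LOW
  succ <- integer(4); succ[p$pairs[, 1]] <- p$pairs[, 2]
  st <- generate_session(p, 20, seed = 31)
  cls <- classify_triplets(st, pattern = p)
  trills <- which(cls$triplet_class == "TRILL_OR_REP")
  expect_true(all(cls$position[trills] != succ[cls$position[trills - 2L]]))
})

test_that("classification requires ordered input and flags missing windows", {
  p <- asrt_pattern(1:4)
  tr <- manual_block(c(1, 2, 3))
  expect_error(classify_triplets(tr[c(2, 1, 3:8), ], pattern = p), "ordered")
  # a block whose first retained trials lack two same-block predecessors
  frag <- data.frame(block = 2L, index_in_block = 8:11,
                     position = c(1L, 2L, 3L, 4L), origin = "random")
  clf <- classify_triplets(frag, pattern = p)
  expect_identical(clf$triplet_class[1:2], rep("UNCLASSIFIABLE", 2L))
  expect_identical(clf$exclusion_reason[1:2], rep("no_window", 2L))
  expect_false(any(clf$triplet_class[3:4] == "UNCLASSIFIABLE"))
})

test_that("classification is a pure function of positions and pattern", {
  p <- asrt_pattern(c(4, 2, 1, 3))
  st <- generate_session(p, 10, seed = 12)
  a <- classify_triplets(st, pattern = p)
  b <- classify_triplets(st, pattern = p)
  expect_identical(a, b)
  # and the pattern is correctly inferred when not supplied
  expect_identical(classify_triplets(st)$triplet_class, a$triplet_class)
})

test_that("boxplot outlier filter matches a brute-force oracle", {
  p <- asrt_pattern(1:4)
  tr <- with_responses(classify_triplets(generate_session(p, 2, seed = 3),
                                         pattern = p))
  # identical RTs: the closed range contains everything
  out0 <- filter_rt_outliers(tr)
  expect_false(any(out0$exclusion_reason == "rt_outlier"))
  # one extreme value among 99 quiet ones
  inc <- which(tr$included)
  tr2 <- tr
  tr2$rt_first_ms[inc] <- 400
  tr2$rt_first_ms[inc[50]] <- 4000
  out2 <- filter_rt_outliers(tr2)
  expect_identical(which(out2$exclusion_reason == "rt_outlier"), inc[50])
  # random RTs against the definitional quartile oracle
  set.seed(41)
  tr3 <- tr
  tr3$rt_first_ms[inc] <- stats::rlnorm(length(inc), log(400), 0.4)
  out3 <- filter_rt_outliers(tr3, k = 1.5)
  expected <- oracle_box_outliers(tr3$rt_first_ms[inc], k = 1.5)
  expect_identical(out3$exclusion_reason[inc] == "rt_outlier", expected)
  expect_error(filter_rt_outliers(tr, k = -1), "k")
})

test_that("exclusion reasons account for every trial", {
  st <- small_study(seed = 9, n1 = 3, n2 = 3, n_blocks = 10)
  cl <- filter_rt_outliers(classify_triplets(st))
  rep <- exclusion_report(cl)
  cnt <- rep$overall
  expect_identical(unname(cnt[["n_trials"]]), as.numeric(nrow(cl)))
  expect_equal(cnt[["none"]] + cnt[["warmup"]] + cnt[["no_window"]] +
                 cnt[["trill_or_rep"]] + cnt[["rt_outlier"]],
               nrow(cl))
  expect_identical(sum(cl$included), as.integer(cnt[["none"]]))
  expect_true(all(rep$per_participant$prop_outlier_of_classifiable >=
                    rep$per_participant$prop_outlier_of_all))
})

test_that("epoch aggregation computes cellwise medians and accuracies", {
  st <- small_study(seed = 13, n1 = 2, n2 = 2, n_blocks = 40)
  ep <- aggregate_epochs(filter_rt_outliers(classify_triplets(st)))
  expect_identical(nrow(ep), 4L * 8L * 2L)  # participants x epochs x types
  expect_true(all(ep$mean_accuracy >= 0 & ep$mean_accuracy <= 1))
  expect_true(all(ep$median_rt_ms[ep$n_rt_trials > 0] > 0))
  # even-count median is the midpoint of the central pair: a hand-laid
  # block whose two high-probability endpoints carry RTs 300 and 400
  p14 <- asrt_pattern(1:4)  # successors 1->2, 2->3, 3->4, 4->1
  tr <- manual_block(c(1, 3, 2, 2, 3), warmup = rep(3L, 5L))
  cl <- classify_triplets(tr, pattern = p14)
  expect_identical(cl$triplet_class[6:10],
                   c("UNCLASSIFIABLE", "UNCLASSIFIABLE", "HIGH", "LOW",
                     "HIGH"))
  cl <- with_responses(cl, rt = 100)
  cl$rt_first_ms[cl$triplet_class == "HIGH"] <- c(300, 400)
  one <- aggregate_epochs(cl)
  expect_identical(one$median_rt_ms[one$triplet_type == "HIGH"], 350)
})

test_that("noise-free aggregation recovers the response model exactly", {
  p <- asrt_pattern(c(2, 3, 1, 4))
  s <- generate_session(p, 40, seed = 21)
  prm <- learner_params(practice_amp_ms = 0, learn_asymptote_ms = 24,
                        learn_rate = 0.5, noise_sigma = 0, base_error = 0,
                        seed = 5)
  sim <- simulate_participant(s, prm, pattern = p)
  ep <- aggregate_epochs(classify_triplets(sim, pattern = p))
  delta <- 24 * (1 - exp(-0.5 * ep$epoch))
  expect_equal(ep$median_rt_ms,
               ifelse(ep$triplet_type == "HIGH",
                      prm$baseline_rt_ms - delta, prm$baseline_rt_ms),
               tolerance = 1e-12)
})

test_that("learning scores difference the two triplet types", {
  base <- expand.grid(participant_id = "p1", group = "NTP", epoch = 1:2,
                      triplet_type = c("HIGH", "LOW"), stringsAsFactors = FALSE)
  base$median_rt_ms <- c(380, 380, 410, 410)
  base$mean_accuracy <- c(0.95, 0.95, 0.90, 0.90)
  base$n_trials <- 40L
  base$n_rt_trials <- 38L
  sc <- learning_scores(base)
  expect_equal(sc$rt_score_ms, c(30, 30))
  expect_equal(sc$acc_score, c(0.05, 0.05))
  # identical cells give zero scores
  same <- base
  same$median_rt_ms <- 400
  same$mean_accuracy <- 0.9
  expect_true(all(learning_scores(same)$rt_score_ms == 0))
  # a missing cell yields a missing score, never zero
  gap <- base
  gap$n_rt_trials[gap$epoch == 2 & gap$triplet_type == "LOW"] <- 0L
  gap$median_rt_ms[gap$epoch == 2 & gap$triplet_type == "LOW"] <- NA
  sc2 <- learning_scores(gap)
  expect_true(is.na(sc2$rt_score_ms[sc2$epoch == 2]))
})

test_that("the pipeline is invariant to relabeling screen positions", {
  perm <- c(3L, 1L, 4L, 2L)  # fixed relabeling of positions
  p <- asrt_pattern(c(1, 2, 4, 3))
  s <- generate_session(p, 10, seed = 77)
  prm <- learner_params(seed = 6)
  sim <- simulate_participant(s, prm, pattern = p)
  ep1 <- aggregate_epochs(filter_rt_outliers(classify_triplets(sim, p)))
  sim2 <- sim
  sim2$position <- perm[sim$position]
  p2 <- asrt_pattern(perm[p$order])
  ep2 <- aggregate_epochs(filter_rt_outliers(classify_triplets(sim2, p2)))
  expect_equal(ep1, ep2)
})
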