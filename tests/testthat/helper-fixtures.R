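# Shared fixtures built in code.

# A hand-laid single-block trial table: five warm-up trials then an
# explicit position stream starting at index 6.
manual_block <- function(stream, warmup = rep(4L, 5L)) {
  pos <- c(warmup, stream)
  idx <- seq_along(pos)
  data.frame(block = 1L, index_in_block = idx, position = as.integer(pos),
             origin = ifelse(idx <= 5L, "warmup",
                             ifelse((idx - 5L) %% 2L == 1L, "pattern",
                                    "random")),
             stringsAsFactors = FALSE)
}

# Attach dummy response columns so aggregation can run.
with_responses <- function(trials, rt = 400, correct = TRUE) {
  trials$rt_first_ms <- rep_len(rt, nrow(trials))
  trials$first_correct <- rep_len(correct, nrow(trials))
  trials$n_attempts <- ifelse(trials$first_correct, 1L, 2L)
  trials
}

# Small simulated study for pipeline-level tests.
small_study <- function(seed = 1, n1 = 4, n2 = 4, n_blocks = 10, ...) {
  simulate_study(group_spec("NTP", n1, ...), group_spec("ASD", n2, ...),
                 seed = seed, n_blocks = n_blocks)
}
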