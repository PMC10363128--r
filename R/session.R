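#' Generate an ASRT session stimulus stream
#'
#' Builds the trial table for one session: `n_blocks` blocks of 85 trials.
#' Each block starts with five warm-up trials at uniformly random positions,
#' followed by an eight-element alternating unit repeated ten times: pattern
#' trials visit the cycle `pattern$order` in order (restarting at the first
#' cycle element in every block), interleaved with uniformly random trials.
#' Only positions and trial origins are generated; reaction times and
#' correctness are filled in by [simulate_participant()].
#'
#' @param pattern An [asrt_pattern()].
#' @param n_blocks Number of blocks (>= 1); the full task uses 40.
#' @param seed Optional integer seed for the random positions.
#' @return A data frame with `n_blocks * 85` rows and columns `block`,
#'   `index_in_block` (1..85), `position` (1..4), and `origin`
#'   (`"warmup"`, `"pattern"`, or `"random"`).
#' @examples
#' s <- generate_session(asrt_pattern(c(1, 2, 4, 3)), n_blocks = 1, seed = 1)
#' table(s$origin)
#' @export
generate_session <- function(pattern, n_blocks = 40L, seed = NULL) {
  stopifnot(inherits(pattern, "asrt_pattern"))
  n_blocks <- as.integer(n_blocks)
  if (is.na(n_blocks) || n_blocks < 1L) stop("`n_blocks` must be >= 1")
  if (!is.null(seed)) set.seed(as.integer(seed))

  n <- n_blocks * 85L
  idx <- rep(1:85, times = n_blocks)
  origin <- ifelse(idx <= 5L, "warmup",
                   ifelse((idx - 5L) %% 2L == 1L, "pattern", "random"))
  position <- sample.int(4L, n, replace = TRUE)
  # 40 pattern trials per block = 10 cycles of the 4-element order.
  pat_positions <- rep(rep(pattern$order, times = 10L), times = n_blocks)
  position[origin == "pattern"] <- pat_positions
  data.frame(
    block = rep(seq_len(n_blocks), each = 85L),
    index_in_block = idx,
    position = position,
    origin = origin,
    stringsAsFactors = FALSE
  )
}

#' Generate pattern-free practice blocks
#'
#' Participants first perform blocks without the hidden pattern: every trial
#' position is an independent uniform draw. The first five trials of each
#' block are still flagged as warm-up; the rest carry origin `"random"`.
#'
#' @param n_blocks Number of practice blocks (>= 0); the task uses 2.
#' @param seed Optional integer seed.
#' @return A data frame in the same layout as [generate_session()], possibly
#'   with zero rows.
#' @export
generate_practice_blocks <- function(n_blocks = 2L, seed = NULL) {
  n_blocks <- as.integer(n_blocks)
  if (is.na(n_blocks) || n_blocks < 0L) stop("`n_blocks` must be >= 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- n_blocks * 85L
  idx <- rep(1:85, times = n_blocks)
  data.frame(
    block = rep(seq_len(n_blocks), each = 85L)[seq_len(n)],
    index_in_block = idx,
    position = sample.int(4L, n, replace = TRUE),
    origin = ifelse(idx <= 5L, "warmup", "random"),
    stringsAsFactors = FALSE
  )
}

#' Infer the pattern cycle from a trial log
#'
#' Reads the cycle off the first four pattern-origin trials of the earliest
#' block (the cycle restarts at each block's first pattern trial).
#'
#' @param trials A trial table with columns `block`, `index_in_block`,
#'   `position`, `origin` for a single participant.
#' @return An [asrt_pattern()].
#' @export
infer_pattern <- function(trials) {
  pat <- trials[trials$origin == "pattern", , drop = FALSE]
  if (nrow(pat) < 4L) stop("cannot infer pattern: fewer than 4 pattern trials")
  pat <- pat[order(pat$block, pat$index_in_block), ]
  asrt_pattern(pat$position[1:4])
}

#' Session metadata constants
#'
#' Fixed task parameters kept as metadata: trials per block, warm-up trials
#' per block, blocks merged into one epoch, the response-to-stimulus interval
#' in milliseconds, and the epoch after which the mid-session break occurs.
#' None of these timing fields enters any computation; they document the
#' procedure.
#'
#' @return A named list.
#' @export
session_metadata <- function() {
  list(trials_per_block = 85L, warmup_per_block = 5L, blocks_per_epoch = 5L,
       rsi_ms = 120, break_after_epoch = 4L)
}

#' Read or write a trial-log CSV
#'
#' The on-disk schema is one row per trial with the header
#' `participant_id, group, block, index_in_block, position, origin,
#' rt_first_ms, first_correct, n_attempts`. Positions are 1-based,
#' left-to-right on screen.
#'
#' @param trials A trial table.
#' @param path File path.
#' @return `read_trials_csv` returns the trial table; `write_trials_csv`
#'   returns `path` invisibly.
#' @export
write_trials_csv <- function(trials, path) {
  cols <- c("participant_id", "group", "block", "index_in_block", "position",
            "origin", "rt_first_ms", "first_correct", "n_attempts")
  missing_cols <- setdiff(cols, names(trials))
  for (cc in missing_cols) trials[[cc]] <- NA
  utils::write.csv(trials[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("first_correct" %in% names(tr)) {
    tr$first_correct <- as.logical(tr$first_correct)
  }
  tr
}
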