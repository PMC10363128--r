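# Core sliding-window classifier. Trials must be sorted by block then
# index_in_block; the window never crosses a block boundary and never
# reaches into the warm-up trials (index <= 5), so the first classifiable
# endpoint of a block is index 8. This keeps the generated occurrence
# probabilities at their exact task values (pattern-ending endpoints are
# HIGH with certainty).
.triplet_class <- function(block, idx, position, pattern) {
  succ <- .pattern_successor(pattern)
  n <- length(position)
  cls <- rep("UNCLASSIFIABLE", n)
  if (n < 3L) return(cls)
  i <- 3:n
  two_back <- c(NA_integer_, NA_integer_, position[i - 2L])
  same_block <- c(FALSE, FALSE, block[i - 2L] == block[i] &
                    idx[i] - idx[i - 2L] == 2L)
  endpoint <- idx > 7L & same_block
  high <- endpoint & succ[ifelse(is.na(two_back), 1L, two_back)] == position
  trill <- endpoint & two_back == position
  cls[endpoint] <- "LOW"
  cls[which(high)] <- "HIGH"
  cls[which(trill)] <- "TRILL_OR_REP"   # precedence; disjoint from HIGH
  cls
}

#' Classify trials by triplet probability
#'
#' Labels every trial, in a sliding-window manner, by the triplet it
#' completes: `HIGH` if its two-back position and its own position form a
#' pattern transition, `TRILL_OR_REP` if the two positions coincide (trills
#' such as 2-1-2 and repetitions such as 2-2-2, which are excluded because
#' of pre-existing response tendencies), `LOW` otherwise, and
#' `UNCLASSIFIABLE` for warm-up trials and trials without two same-block
#' post-warm-up predecessors. The window advances one trial at a time, so in
#' the stream 1 3 2 1 4 ... trial 3 is judged from trials 1-3, trial 4 from
#' trials 2-4, and so on. Windows never cross a block boundary and never
#' reach into the warm-up trials, so the first classifiable endpoint of a
#' standard block is trial 8; this keeps pattern-ending endpoints
#' high-probability with certainty and the occurrence probabilities at their
#' exact task values.
#'
#' @param trials Trial table, ordered by block then `index_in_block` within
#'   each participant. May contain several participants (column
#'   `participant_id`).
#' @param pattern An [asrt_pattern()], or `NULL` to infer each participant's
#'   pattern from their pattern-origin trials.
#' @return The trial table with columns `triplet_class`, `included`
#'   (logical), and `exclusion_reason` (`"none"`, `"warmup"`, `"no_window"`,
#'   `"trill_or_rep"`; RT outliers are flagged later by
#'   [filter_rt_outliers()]).
#' @export
classify_triplets <- function(trials, pattern = NULL) {
  if (!all(c("block", "index_in_block", "position") %in% names(trials))) {
    stop("`trials` must have block, index_in_block, position")
  }
  one <- function(tr, pat) {
    o <- order(tr$block, tr$index_in_block)
    if (any(o != seq_len(nrow(tr)))) {
      stop("trials must be ordered by block then index_in_block")
    }
    if (is.null(pat)) pat <- infer_pattern(tr)
    tr$triplet_class <- .triplet_class(tr$block, tr$index_in_block,
                                       tr$position, pat)
    tr$exclusion_reason <- ifelse(
      tr$triplet_class == "TRILL_OR_REP", "trill_or_rep",
      ifelse(tr$triplet_class != "UNCLASSIFIABLE", "none",
             ifelse(tr$index_in_block <= 5L, "warmup", "no_window")))
    tr$included <- tr$exclusion_reason == "none"
    tr
  }
  if ("participant_id" %in% names(trials) &&
      length(unique(trials$participant_id)) > 1L) {
    parts <- split(trials, trials$participant_id)
    out <- do.call(rbind, lapply(parts, one, pat = pattern))
    rownames(out) <- NULL
    out[order(match(out$participant_id, unique(trials$participant_id))), ]
  } else {
    one(trials, pattern)
  }
}

#' Flag reaction-time outliers by the boxplot rule
#'
#' Within each participant, the first and third quartiles and the
#' inter-quartile distance (IQD) are computed over the reaction times of the
#' trials still included after classification (trills/repetitions and
#' unclassifiable trials are already out). Trials with RT below
#' `Q1 - k * IQD` or above `Q3 + k * IQD` are flagged `rt_outlier` and
#' excluded. Quartiles are computed once, in a single pass: the flagging is
#' not re-iterated on the filtered sample.
#'
#' @param trials Output of [classify_triplets()] with `rt_first_ms` set.
#' @param k Whisker multiplier (default 1.5).
#' @return The trial table with outliers flagged.
#' @export
filter_rt_outliers <- function(trials, k = 1.5) {
  if (k < 0) stop("`k` must be >= 0")
  if (!all(c("included", "rt_first_ms") %in% names(trials))) {
    stop("run classify_triplets() first and provide rt_first_ms")
  }
  pid <- if ("participant_id" %in% names(trials)) trials$participant_id
         else rep("p1", nrow(trials))
  inc <- trials$included
  q1 <- tapply(trials$rt_first_ms[inc], pid[inc], stats::quantile,
               probs = 0.25, na.rm = TRUE)
  q3 <- tapply(trials$rt_first_ms[inc], pid[inc], stats::quantile,
               probs = 0.75, na.rm = TRUE)
  lo <- q1 - k * (q3 - q1)
  hi <- q3 + k * (q3 - q1)
  i <- match(pid, names(q1))
  out <- inc & (trials$rt_first_ms < lo[i] | trials$rt_first_ms > hi[i])
  out[is.na(out)] <- FALSE
  trials$exclusion_reason[out] <- "rt_outlier"
  trials$included[out] <- FALSE
  trials
}

#' Aggregate classified trials into epoch summaries
#'
#' Blocks are merged into epochs (`blocks_per_epoch` consecutive blocks per
#' epoch; epoch `e` covers blocks `blocks_per_epoch*(e-1)+1` to
#' `blocks_per_epoch*e`). Within each participant x epoch x triplet-type
#' cell, the median RT is computed over included trials whose first response
#' was correct, and the mean accuracy is the proportion of correct first
#' responses over all included trials of the cell. Cells with no eligible
#' trials get `n_trials = 0` and missing summary values; they are never
#' imputed.
#'
#' @param trials Output of [filter_rt_outliers()] (or [classify_triplets()]
#'   if no outlier filtering is wanted).
#' @param blocks_per_epoch Blocks per epoch (default 5).
#' @return A data frame with one row per participant x epoch x triplet type:
#'   `participant_id`, `group`, `epoch`, `triplet_type` (`"HIGH"`/`"LOW"`),
#'   `median_rt_ms`, `mean_accuracy`, `n_trials` (included trials of the
#'   cell), `n_rt_trials` (correct included trials entering the median).
#' @export
aggregate_epochs <- function(trials, blocks_per_epoch = 5L) {
  blocks_per_epoch <- as.integer(blocks_per_epoch)
  if (blocks_per_epoch < 1L) stop("blocks_per_epoch must be >= 1")
  need <- c("included", "triplet_class", "rt_first_ms", "first_correct")
  if (!all(need %in% names(trials))) {
    stop("trials must be classified and carry rt_first_ms / first_correct")
  }
  if (!"participant_id" %in% names(trials)) trials$participant_id <- "p1"
  if (!"group" %in% names(trials)) trials$group <- NA_character_
  inc <- trials[trials$included & trials$triplet_class %in% c("HIGH", "LOW"), ]
  inc$epoch <- (inc$block - 1L) %/% blocks_per_epoch + 1L

  pids <- unique(trials$participant_id)
  grp <- trials$group[match(pids, trials$participant_id)]
  epochs <- seq_len(max((max(trials$block) - 1L) %/% blocks_per_epoch + 1L, 1L))
  grid <- expand.grid(participant_id = pids, epoch = epochs,
                      triplet_type = c("HIGH", "LOW"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$group <- grp[match(grid$participant_id, pids)]

  key <- function(p, e, t) paste(p, e, t, sep = "\r")
  inc_key <- key(inc$participant_id, inc$epoch, inc$triplet_class)
  grid_key <- key(grid$participant_id, grid$epoch, grid$triplet_type)

  n_trials <- tapply(rep(1L, nrow(inc)), inc_key, sum)
  acc <- tapply(inc$first_correct, inc_key, mean)
  ok <- inc[inc$first_correct, ]
  ok_key <- key(ok$participant_id, ok$epoch, ok$triplet_class)
  med <- tapply(ok$rt_first_ms, ok_key, stats::median)
  n_rt <- tapply(rep(1L, nrow(ok)), ok_key, sum)

  grid$median_rt_ms <- as.numeric(med[grid_key])
  grid$mean_accuracy <- as.numeric(acc[grid_key])
  grid$n_trials <- ifelse(is.na(n_trials[grid_key]), 0L,
                          as.integer(n_trials[grid_key]))
  grid$n_rt_trials <- ifelse(is.na(n_rt[grid_key]), 0L,
                             as.integer(n_rt[grid_key]))
  grid <- grid[order(match(grid$participant_id, pids), grid$epoch,
                     grid$triplet_type), ]
  rownames(grid) <- NULL
  grid[, c("participant_id", "group", "epoch", "triplet_type",
           "median_rt_ms", "mean_accuracy", "n_trials", "n_rt_trials")]
}

#' Per-epoch statistical learning scores
#'
#' The RT learning score of an epoch is the low-probability minus the
#' high-probability median RT (positive when the participant responds faster
#' to predictable trials); the accuracy score is the high- minus the
#' low-probability mean accuracy. Scores are missing -- never zero -- when
#' either cell of the epoch is empty.
#'
#' @param summaries Output of [aggregate_epochs()].
#' @return A data frame with columns `participant_id`, `group`, `epoch`,
#'   `rt_score_ms`, `acc_score`.
#' @export
learning_scores <- function(summaries) {
  hi <- summaries[summaries$triplet_type == "HIGH", ]
  lo <- summaries[summaries$triplet_type == "LOW", ]
  m <- merge(hi, lo, by = c("participant_id", "group", "epoch"),
             suffixes = c("_high", "_low"))
  m$rt_score_ms <- ifelse(m$n_rt_trials_high > 0L & m$n_rt_trials_low > 0L,
                          m$median_rt_ms_low - m$median_rt_ms_high, NA_real_)
  m$acc_score <- ifelse(m$n_trials_high > 0L & m$n_trials_low > 0L,
                        m$mean_accuracy_high - m$mean_accuracy_low, NA_real_)
  m <- m[order(m$participant_id, m$epoch),
         c("participant_id", "group", "epoch", "rt_score_ms", "acc_score")]
  rownames(m) <- NULL
  m
}

#' Exclusion report
#'
#' Tabulates, per participant and overall, how many trials were dropped at
#' each stage of the preprocessing chain (warm-up, missing window,
#' trill/repetition, RT outlier) and the corresponding proportions. Two
#' readings of the outlier percentage are reported: outliers as a share of
#' all trials, and as a share of the classifiable (non-trill) trials the
#' boxplot rule was applied to.
#'
#' @param trials Output of [filter_rt_outliers()].
#' @return A list with elements `overall` (named counts and proportions) and
#'   `per_participant` (data frame).
#' @export
exclusion_report <- function(trials) {
  if (!"participant_id" %in% names(trials)) trials$participant_id <- "p1"
  reasons <- c("none", "warmup", "no_window", "trill_or_rep", "rt_outlier")
  count_one <- function(tr) {
    n <- nrow(tr)
    cnt <- vapply(reasons, function(r) sum(tr$exclusion_reason == r),
                  integer(1L))
    at_risk <- cnt[["none"]] + cnt[["rt_outlier"]]
    c(n_trials = n, cnt,
      prop_outlier_of_all = unname(cnt[["rt_outlier"]]) / n,
      prop_outlier_of_classifiable = if (at_risk > 0)
        unname(cnt[["rt_outlier"]]) / at_risk else NA_real_,
      prop_included = unname(cnt[["none"]]) / n)
  }
  per <- t(vapply(split(trials, trials$participant_id), count_one,
                  numeric(9L)))
  per_df <- data.frame(participant_id = rownames(per), per,
                       row.names = NULL, check.names = FALSE)
  list(overall = as.list(count_one(trials)), per_participant = per_df)
}

#' Write an epoch-summary CSV
#'
#' @param summaries Output of [aggregate_epochs()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_epochs_csv <- function(summaries, path) {
  utils::write.csv(summaries, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
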