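#' Response-model parameters for one synthetic participant
#'
#' The simulator's response model combines three standard reaction-time
#' phenomena: a power-law practice curve over blocks, a saturating
#' (exponential-approach) statistical-learning advantage for trials that end
#' a high-probability triplet, and multiplicative lognormal trial noise. The
#' mean RT of a trial in block `b` of epoch `e` is
#' \deqn{\mu(b, e) = baseline + amp \cdot b^{-decay} - \Delta(e) \cdot
#'   1[\mathrm{HIGH}]}{mu(b,e) = baseline + amp * b^-decay - Delta(e) * 1[HIGH]}
#' with \eqn{\Delta(e) = asymptote \cdot (1 - e^{-rate \cdot e})}. The
#' realized RT is `max(floor_rt_ms, mu * exp(eps))` with
#' `eps ~ Normal(0, noise_sigma)`. The first response is correct with
#' probability `1 - p_err`, where
#' `p_err = clip(base_error - error_reduction * (1 - exp(-learn_rate * e)) *
#' 1[HIGH], 0.001, 0.5)`; after an error the participant guesses until
#' correct, adding a geometric (success probability 3/4) number of extra
#' attempts.
#'
#' @param baseline_rt_ms Asymptotic mean RT in ms (positive).
#' @param practice_amp_ms Amplitude of the practice curve in ms (>= 0).
#' @param practice_decay Power-law exponent over blocks (> 0).
#' @param learn_asymptote_ms Asymptotic high-vs-low RT advantage in ms (>= 0).
#' @param learn_rate Per-epoch saturation rate of the advantage (>= 0).
#' @param noise_sigma Scale of the multiplicative lognormal RT noise (>= 0).
#' @param base_error Baseline first-response error probability, in [0, 0.5].
#' @param error_reduction Asymptotic accuracy advantage for high-probability
#'   trials (>= 0).
#' @param floor_rt_ms Hard lower bound on simulated RTs in ms (positive).
#' @param seed Optional integer seed used by [simulate_participant()].
#' @return A validated list of class `learner_params`.
#' @export
learner_params <- function(baseline_rt_ms = 380, practice_amp_ms = 120,
                           practice_decay = 0.3, learn_asymptote_ms = 30,
                           learn_rate = 0.5, noise_sigma = 0.18,
                           base_error = 0.08, error_reduction = 0.04,
                           floor_rt_ms = 150, seed = NULL) {
  p <- list(baseline_rt_ms = baseline_rt_ms, practice_amp_ms = practice_amp_ms,
            practice_decay = practice_decay,
            learn_asymptote_ms = learn_asymptote_ms, learn_rate = learn_rate,
            noise_sigma = noise_sigma, base_error = base_error,
            error_reduction = error_reduction, floor_rt_ms = floor_rt_ms,
            seed = seed)
  if (p$baseline_rt_ms <= 0) stop("baseline_rt_ms must be positive")
  if (p$practice_amp_ms < 0) stop("practice_amp_ms must be >= 0")
  if (p$practice_decay <= 0) stop("practice_decay must be > 0")
  if (p$learn_asymptote_ms < 0) stop("learn_asymptote_ms must be >= 0")
  if (p$learn_rate < 0) stop("learn_rate must be >= 0")
  if (p$noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (p$base_error < 0 || p$base_error > 0.5) {
    stop("base_error must lie in [0, 0.5]")
  }
  if (p$error_reduction < 0) stop("error_reduction must be >= 0")
  if (p$floor_rt_ms <= 0) stop("floor_rt_ms must be positive")
  class(p) <- "learner_params"
  p
}

# Valid ranges used when drawing participant-level parameters.
.param_bounds <- list(
  baseline_rt_ms = c(160, Inf), practice_amp_ms = c(0, Inf),
  practice_decay = c(0.05, Inf), learn_asymptote_ms = c(0, Inf),
  learn_rate = c(0, Inf), noise_sigma = c(0, Inf),
  base_error = c(0.001, 0.5), error_reduction = c(0, 0.5),
  floor_rt_ms = c(50, Inf)
)

#' Group-level specification for a simulated study
#'
#' Defines one group of synthetic participants: its label, size, and the
#' between-participant distribution (normal, truncated to valid ranges) of
#' every [learner_params()] field.
#'
#' @param label Group label, `"NTP"` (neurotypical) or `"ASD"`.
#' @param n_participants Number of participants (>= 2). Defaults follow the
#'   study sample: 20 neurotypical and 22 autistic adults.
#' @param means Named list overriding selected mean parameters; unnamed
#'   fields keep the [learner_params()] defaults.
#' @param sds Named list overriding selected between-participant standard
#'   deviations (>= 0).
#' @return A list of class `group_spec`.
#' @export
group_spec <- function(label = c("NTP", "ASD"), n_participants = NULL,
                       means = list(), sds = list()) {
  label <- match.arg(label)
  if (is.null(n_participants)) {
    n_participants <- if (label == "NTP") 20L else 22L
  }
  n_participants <- as.integer(n_participants)
  if (n_participants < 2L) stop("n_participants must be >= 2")
  mean_def <- unclass(learner_params())
  mean_def$seed <- NULL
  sd_def <- list(baseline_rt_ms = 40, practice_amp_ms = 30,
                 practice_decay = 0.08, learn_asymptote_ms = 10,
                 learn_rate = 0.15, noise_sigma = 0.03, base_error = 0.02,
                 error_reduction = 0.015, floor_rt_ms = 0)
  bad <- setdiff(names(means), names(mean_def))
  if (length(bad)) stop("unknown parameter(s) in `means`: ",
                        paste(bad, collapse = ", "))
  bad <- setdiff(names(sds), names(sd_def))
  if (length(bad)) stop("unknown parameter(s) in `sds`: ",
                        paste(bad, collapse = ", "))
  mean_def[names(means)] <- means
  sd_def[names(sds)] <- sds
  if (any(unlist(sd_def) < 0)) stop("parameter sds must be >= 0")
  structure(list(label = label, n_participants = n_participants,
                 means = mean_def, sds = sd_def), class = "group_spec")
}

# Draw one participant's parameters from a group spec.
.draw_params <- function(spec, seed, response_seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  fields <- names(.param_bounds)
  vals <- lapply(fields, function(f) {
    v <- stats::rnorm(1L, spec$means[[f]], spec$sds[[f]])
    b <- .param_bounds[[f]]
    min(max(v, b[1L]), b[2L])
  })
  names(vals) <- fields
  vals$baseline_rt_ms <- max(vals$baseline_rt_ms, vals$floor_rt_ms + 10)
  do.call(learner_params, c(vals, list(seed = response_seed)))
}

#' Simulate one participant's responses
#'
#' Fills reaction times, first-response correctness, and attempt counts into
#' a stimulus stream generated by [generate_session()], under the response
#' model described in [learner_params()]. The statistical-learning advantage
#' applies to trials ending a high-probability triplet under the sliding
#' window classification (warm-up endpoints and trills/repetitions receive
#' no advantage).
#'
#' @param session Trial table with positions and origins set.
#' @param params A [learner_params()].
#' @param pattern The [asrt_pattern()] the session was generated from; if
#'   `NULL` it is inferred from the pattern-origin trials.
#' @param blocks_per_epoch Blocks merged into one epoch of analysis
#'   (default 5).
#' @return The trial table with columns `rt_first_ms`, `first_correct`, and
#'   `n_attempts` filled in. Deterministic given `params$seed`.
#' @export
simulate_participant <- function(session, params, pattern = NULL,
                                 blocks_per_epoch = 5L) {
  stopifnot(inherits(params, "learner_params"))
  if (!all(c("block", "index_in_block", "position", "origin") %in%
           names(session))) {
    stop("`session` must have block, index_in_block, position, origin")
  }
  if (nrow(session) == 0L) stop("`session` has no trials")
  if (any(is.na(session$position))) stop("session positions must be set")
  if (!is.null(params$seed)) set.seed(as.integer(params$seed))
  if (is.null(pattern)) {
    pattern <- if (any(session$origin == "pattern")) infer_pattern(session)
               else asrt_pattern(1:4)
  }

  n <- nrow(session)
  b <- session$block
  e <- (b - 1L) %/% as.integer(blocks_per_epoch) + 1L
  cls <- .triplet_class(session$block, session$index_in_block,
                        session$position, pattern)
  is_high <- cls == "HIGH"

  delta <- params$learn_asymptote_ms * (1 - exp(-params$learn_rate * e))
  mu <- params$baseline_rt_ms +
    params$practice_amp_ms * b ^ (-params$practice_decay) -
    delta * is_high
  rt <- pmax(params$floor_rt_ms,
             mu * exp(stats::rnorm(n, 0, params$noise_sigma)))

  p_err <- params$base_error -
    params$error_reduction * (1 - exp(-params$learn_rate * e)) * is_high
  p_err <- pmin(pmax(p_err, 0.001), 0.5)
  correct <- stats::runif(n) >= p_err
  n_attempts <- rep(1L, n)
  n_wrong <- sum(!correct)
  if (n_wrong > 0L) {
    n_attempts[!correct] <- 2L + stats::rgeom(n_wrong, 0.75)
  }

  session$rt_first_ms <- rt
  session$first_correct <- correct
  session$n_attempts <- n_attempts
  session
}

#' Simulate a two-group ASRT study
#'
#' Draws participant-level response parameters from each group's
#' distribution, generates an independent session (with, by default, an
#' independent uniformly random pattern cycle) per participant, and simulates
#' all responses. Everything is reproducible from `seed`.
#'
#' @param ntp,asd [group_spec()] objects for the two groups.
#' @param seed Master integer seed.
#' @param n_blocks Blocks per participant (default 40, the full task).
#' @param blocks_per_epoch Blocks per epoch of analysis (default 5).
#' @param pattern Either `"random"` (default: an independent random cycle per
#'   participant) or a single [asrt_pattern()] shared by everyone.
#' @return A trial table for all participants with columns `participant_id`,
#'   `group`, `block`, `index_in_block`, `position`, `origin`, `rt_first_ms`,
#'   `first_correct`, `n_attempts`.
#' @examples
#' trials <- simulate_study(group_spec("NTP", 2), group_spec("ASD", 2),
#'                          seed = 1, n_blocks = 5)
#' nrow(trials)  # 4 participants x 5 blocks x 85 trials
#' @export
simulate_study <- function(ntp = group_spec("NTP"), asd = group_spec("ASD"),
                           seed = 1L, n_blocks = 40L, blocks_per_epoch = 5L,
                           pattern = "random") {
  stopifnot(inherits(ntp, "group_spec"), inherits(asd, "group_spec"))
  if (ntp$label == asd$label) stop("group labels must differ")
  set.seed(as.integer(seed))
  specs <- list(ntp, asd)
  n_total <- ntp$n_participants + asd$n_participants
  # Independent sub-seeds per participant: parameters, pattern, stream,
  # responses.
  part_seeds <- matrix(sample.int(.Machine$integer.max - 1L, 4L * n_total),
                       ncol = 4L)
  out <- vector("list", n_total)
  k <- 0L
  for (spec in specs) {
    for (i in seq_len(spec$n_participants)) {
      k <- k + 1L
      params <- .draw_params(spec, seed = part_seeds[k, 1L],
                             response_seed = part_seeds[k, 4L])
      pat <- if (identical(pattern, "random")) {
        asrt_pattern(seed = part_seeds[k, 2L])
      } else {
        stopifnot(inherits(pattern, "asrt_pattern"))
        pattern
      }
      session <- generate_session(pat, n_blocks = n_blocks,
                                  seed = part_seeds[k, 3L])
      trials <- simulate_participant(session, params, pattern = pat,
                                     blocks_per_epoch = blocks_per_epoch)
      trials$participant_id <- sprintf("%s_%02d", tolower(spec$label), i)
      trials$group <- spec$label
      out[[k]] <- trials[, c("participant_id", "group", "block",
                             "index_in_block", "position", "origin",
                             "rt_first_ms", "first_correct", "n_attempts")]
    }
  }
  do.call(rbind, out)
}
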