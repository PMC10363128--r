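#' Create an ASRT pattern sequence
#'
#' The alternating serial reaction time (ASRT) task hides a four-element
#' pattern cycle among random stimuli: every other trial follows the cycle,
#' the rest are drawn uniformly from the four screen positions. The cycle is
#' a permutation of the positions 1..4; it induces four ordered
#' pattern transitions `(order[i], order[i + 1 mod 4])` which define which
#' stimulus triplets are high-probability.
#'
#' @param order Integer vector of length 4: an explicit permutation of
#'   `1:4`. If `NULL`, a uniformly random permutation is drawn.
#' @param seed Optional integer seed used when `order` is `NULL`.
#' @return An object of class `asrt_pattern`: a list with elements `order`
#'   (the cycle) and `pairs` (a 4x2 integer matrix of pattern transitions).
#' @examples
#' p <- asrt_pattern(c(1, 2, 4, 3))
#' pattern_transitions(p)
#' @export
asrt_pattern <- function(order = NULL, seed = NULL) {
  if (is.null(order)) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    order <- sample.int(4L)
  }
  order <- as.integer(order)
  if (length(order) != 4L || !setequal(order, 1:4)) {
    stop("`order` must be a permutation of 1:4, got: ",
         paste(order, collapse = ", "))
  }
  pairs <- cbind(from = order, to = order[c(2:4, 1)])
  structure(list(order = order, pairs = pairs), class = "asrt_pattern")
}

#' @export
print.asrt_pattern <- function(x, ...) {
  cat("ASRT pattern cycle:", paste(x$order, collapse = " "), "\n")
  cat("Pattern transitions:",
      paste(sprintf("(%d,%d)", x$pairs[, 1], x$pairs[, 2]), collapse = " "),
      "\n")
  invisible(x)
}

#' Pattern transitions of a cycle
#'
#' @param pattern An [asrt_pattern()].
#' @return A 4x2 integer matrix with columns `from` and `to`.
#' @export
pattern_transitions <- function(pattern) {
  stopifnot(inherits(pattern, "asrt_pattern"))
  pattern$pairs
}

# Pattern successor lookup: succ[i] is the position following i in the cycle.
.pattern_successor <- function(pattern) {
  succ <- integer(4L)
  succ[pattern$pairs[, 1L]] <- pattern$pairs[, 2L]
  succ
}

#' Enumerate all 64 ordered stimulus triplets
#'
#' A triplet is three consecutive stimulus positions; it is classified by its
#' first and third elements alone. It is high-probability when the third
#' element is the pattern successor of the first, low-probability otherwise.
#' Triplets whose first and third elements coincide are trills (a-b-a) or
#' repetitions (a-a-a); they are always low-probability because the cycle
#' never maps a position to itself.
#'
#' @param pattern An [asrt_pattern()].
#' @return A data frame with 64 rows and columns `first`, `middle`, `third`,
#'   `high` (logical), and `trill_or_rep` (logical).
#' @export
enumerate_triplets <- function(pattern) {
  stopifnot(inherits(pattern, "asrt_pattern"))
  succ <- .pattern_successor(pattern)
  g <- expand.grid(third = 1:4, middle = 1:4, first = 1:4,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("first", "middle", "third")]
  g$high <- succ[g$first] == g$third
  g$trill_or_rep <- g$first == g$third
  g
}

#' Triplet census for a pattern
#'
#' Counts of high- and low-probability triplets over all 64 ordered triplets
#' (the raw high/low split by the pattern-transition rule), together with the
#' number of trill/repetition triplets. For every pattern cycle the census is
#' 16 high, 48 low, and 16 trill/repetition (all of which are low).
#'
#' @param pattern An [asrt_pattern()].
#' @return Named integer vector with elements `high`, `low`, `trill_or_rep`,
#'   and `total`.
#' @export
triplet_census <- function(pattern) {
  tr <- enumerate_triplets(pattern)
  c(high = sum(tr$high),
    low = sum(!tr$high),
    trill_or_rep = sum(tr$trill_or_rep),
    total = nrow(tr))
}

#' Analytic triplet occurrence probabilities
#'
#' Exact occurrence probabilities under the alternating generative process,
#' computed over classifiable trials (trials whose three-trial window lies
#' entirely after the block's warm-up trials). Pattern trials and random
#' trials each contribute half of the classifiable trials. A pattern-ending
#' triplet spans pattern-random-pattern, so its first and third elements are
#' consecutive cycle elements: it is high-probability with certainty. A
#' random-ending triplet spans random-pattern-random and its third element is
#' uniform over the four positions, so it is high-probability with
#' probability 1/4.
#'
#' @param pattern An [asrt_pattern()]. The probabilities are the same for
#'   every cycle; the argument fixes which triplets are high.
#' @return A named list of exact probabilities: `overall_high` (0.625),
#'   `overall_low` (0.375), `pattern_ending_high_share` (0.5, share of all
#'   classifiable trials), `random_ending_high_share` (0.125),
#'   `per_unique_high` (overall_high / 16), `per_unique_low`
#'   (overall_low / 48).
#' @export
analytic_occurrence <- function(pattern) {
  stopifnot(inherits(pattern, "asrt_pattern"))
  n_high <- sum(enumerate_triplets(pattern)$high)
  n_low <- 64L - n_high
  # Classifiable trials alternate pattern/random in equal shares.
  p_pattern_trial <- 1 / 2
  p_high_given_pattern <- 1       # two-back is the cycle predecessor
  p_high_given_random <- 1 / 4    # uniform draw hits the successor
  pattern_share <- p_pattern_trial * p_high_given_pattern
  random_share <- (1 - p_pattern_trial) * p_high_given_random
  overall_high <- pattern_share + random_share
  list(
    overall_high = overall_high,
    overall_low = 1 - overall_high,
    pattern_ending_high_share = pattern_share,
    random_ending_high_share = random_share,
    per_unique_high = overall_high / n_high,
    per_unique_low = (1 - overall_high) / n_low
  )
}

#' All 24 pattern cycles
#'
#' @return A list of the 24 `asrt_pattern` objects, one per permutation of
#'   1:4.
#' @export
all_patterns <- function() {
  perms <- list()
  for (a in 1:4) for (b in setdiff(1:4, a)) for (ch in setdiff(1:4, c(a, b))) {
    d <- setdiff(1:4, c(a, b, ch))
    perms[[length(perms) + 1L]] <- asrt_pattern(c(a, b, ch, d))
  }
  perms
}
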