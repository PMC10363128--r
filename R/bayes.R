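# The seven candidate fixed effects of the 2 (group) x 8 (epoch) x 2
# (triplet) design, in a canonical order.
.bf_terms <- c("Group", "Epoch", "Triplet", "Group:Epoch", "Group:Triplet",
               "Epoch:Triplet", "Group:Epoch:Triplet")

.term_factors <- function(term) strsplit(term, ":", fixed = TRUE)[[1L]]

# TRUE if `a`'s factor set is a strict subset of `b`'s.
.strict_subset <- function(a, b) {
  fa <- .term_factors(a); fb <- .term_factors(b)
  all(fa %in% fb) && length(fa) < length(fb)
}

# All subsets of the seven terms that respect marginality: a term may enter
# only together with every lower-order term it contains.
.hierarchical_models <- function() {
  n <- length(.bf_terms)
  models <- list()
  for (mask in 0:(2^n - 1L)) {
    terms <- .bf_terms[bitwAnd(bitwShiftR(mask, 0:(n - 1L)), 1L) == 1L]
    ok <- all(vapply(terms, function(tm) {
      lower <- Filter(function(o) .strict_subset(o, tm), .bf_terms)
      all(lower %in% terms)
    }, logical(1L)))
    if (ok) models[[length(models) + 1L]] <- terms
  }
  models
}

#' BIC-scored model space for the mixed design
#'
#' Enumerates every sub-model of the full group x epoch x triplet factorial
#' that respects marginality (19 models, including the null), fits each by
#' least squares with fixed subject blocking (every model contains the
#' subject factor; the null model contains nothing else), and scores it by
#' BIC. The Bayes factor of each model against the null uses the BIC
#' approximation `BF = exp((BIC_null - BIC_model) / 2)`, which corresponds
#' to a unit-information prior on the model parameters. Models get equal
#' prior probabilities; posterior probabilities are the normalized products
#' of prior and Bayes factor.
#'
#' Because subjects are nested in groups, the subject blocking absorbs the
#' group main effect: models differing only in the `Group` term receive
#' identical BICs, so the group main effect itself carries no Bayes-factor
#' evidence under this scheme (its interactions do).
#'
#' @param summaries Output of [aggregate_epochs()].
#' @param dv `"median_rt_ms"` or `"mean_accuracy"`.
#' @return A data frame with one row per model: `model` (label, `"null"` or
#'   `+`-joined terms), `n_terms`, `bic`, `bf_vs_null`, `prior_prob`,
#'   `posterior_prob`.
#' @export
bf_model_space <- function(summaries, dv = "median_rt_ms") {
  d <- .anova_frame(summaries, dv)
  models <- .hierarchical_models()
  term_map <- c(Group = "group", Epoch = "epoch", Triplet = "triplet",
                `Group:Epoch` = "group:epoch",
                `Group:Triplet` = "group:triplet",
                `Epoch:Triplet` = "epoch:triplet",
                `Group:Epoch:Triplet` = "group:epoch:triplet")
  bics <- vapply(models, function(terms) {
    rhs <- paste(c("pid", unname(term_map[terms])), collapse = " + ")
    fit <- stats::lm(stats::as.formula(paste("y ~", rhs)), data = d)
    stats::BIC(fit)
  }, numeric(1L))
  labels <- vapply(models, function(terms) {
    if (length(terms) == 0L) "null" else paste(terms, collapse = " + ")
  }, character(1L))
  bic_null <- bics[labels == "null"]
  bf <- exp((bic_null - bics) / 2)
  prior <- rep(1 / length(models), length(models))
  post <- prior * bf / sum(prior * bf)
  out <- data.frame(model = labels, n_terms = lengths(models), bic = bics,
                    bf_vs_null = bf, prior_prob = prior,
                    posterior_prob = post, stringsAsFactors = FALSE)
  attr(out, "model_terms") <- models
  out
}

#' Exclusion Bayes factor across matched models
#'
#' Evidence for omitting one effect, computed across matched models: the
#' models that contain the effect but no higher-order interaction involving
#' it are compared with the same models with the effect removed.
#' `BF_excl` is the posterior odds of the excluding set over the including
#' set, divided by the corresponding prior odds. Values above 1 favour
#' dropping the effect (above 3: substantial evidence for its absence);
#' values below 1 favour keeping it (below 1/3: substantial evidence for its
#' presence); see [bf_interpret()].
#'
#' @param space Output of [bf_model_space()].
#' @param effect One of `"Group"`, `"Epoch"`, `"Triplet"`, `"Group:Epoch"`,
#'   `"Group:Triplet"`, `"Epoch:Triplet"`, `"Group:Epoch:Triplet"`.
#' @return The exclusion Bayes factor (positive scalar).
#' @export
exclusion_bf <- function(space, effect) {
  models <- attr(space, "model_terms")
  if (is.null(models)) stop("`space` must come from bf_model_space()")
  if (!effect %in% .bf_terms) {
    stop("unknown effect: ", effect, " (expected one of ",
         paste(.bf_terms, collapse = ", "), ")")
  }
  higher <- Filter(function(o) .strict_subset(effect, o), .bf_terms)
  with_eff <- vapply(models, function(tm) {
    effect %in% tm && !any(higher %in% tm)
  }, logical(1L))
  # the matched partners: same models with the effect stripped
  stripped <- lapply(models[with_eff], function(tm) setdiff(tm, effect))
  key <- function(tm) paste(sort(tm), collapse = "|")
  model_keys <- vapply(models, key, character(1L))
  without_eff <- model_keys %in% vapply(stripped, key, character(1L))
  if (!any(with_eff) || !any(without_eff)) {
    stop("no matched model pair for effect ", effect)
  }
  post_in <- sum(space$posterior_prob[with_eff])
  post_out <- sum(space$posterior_prob[without_eff])
  prior_in <- sum(space$prior_prob[with_eff])
  prior_out <- sum(space$prior_prob[without_eff])
  (post_out / post_in) * (prior_in / prior_out)
}

#' Interpret a Bayes factor
#'
#' Conventional evidential bands for exclusion Bayes factors: above 3,
#' substantial evidence for excluding the effect; 1 to 3, anecdotal for
#' exclusion; 1/3 to 1, anecdotal for inclusion; below 1/3, substantial
#' evidence for including the effect.
#'
#' @param bf Positive scalar Bayes factor.
#' @return A character label.
#' @export
bf_interpret <- function(bf) {
  if (!is.numeric(bf) || length(bf) != 1L || is.na(bf) || bf <= 0) {
    stop("`bf` must be a positive number")
  }
  if (bf > 3) "substantial evidence for exclusion"
  else if (bf >= 1) "anecdotal evidence for exclusion"
  else if (bf >= 1 / 3) "anecdotal evidence for inclusion"
  else "substantial evidence for inclusion"
}
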