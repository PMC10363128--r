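# Internal: validate an epoch-summary table for the mixed design and return
# a long data frame with factors group/epoch/triplet and the dv as `y`.
.anova_frame <- function(summaries, dv) {
  dv <- match.arg(dv, c("median_rt_ms", "mean_accuracy"))
  need <- c("participant_id", "group", "epoch", "triplet_type", dv)
  if (!all(need %in% names(summaries))) {
    stop("summaries must have columns: ", paste(need, collapse = ", "))
  }
  d <- data.frame(
    pid = factor(summaries$participant_id),
    group = factor(summaries$group),
    epoch = factor(summaries$epoch),
    triplet = factor(summaries$triplet_type),
    y = summaries[[dv]]
  )
  if (nlevels(d$group) != 2L) {
    stop("exactly 2 group labels required, found: ",
         paste(levels(d$group), collapse = ", "))
  }
  n_cells <- nlevels(d$epoch) * nlevels(d$triplet)
  by_pid <- split(d, d$pid)
  for (p in names(by_pid)) {
    dp <- by_pid[[p]]
    if (nrow(dp) != n_cells || anyDuplicated(paste(dp$epoch, dp$triplet)) ||
        any(is.na(dp$y))) {
      stop("participant ", p, " does not have a complete set of ",
           n_cells, " epoch x triplet cells")
    }
    if (length(unique(dp$group)) != 1L) {
      stop("participant ", p, " appears under more than one group")
    }
  }
  counts <- table(tapply(as.character(d$group), d$pid, unique))
  if (any(counts < 2L)) stop("each group needs >= 2 participants")
  d
}

#' Mixed-design repeated-measures ANOVA
#'
#' The study's central test: a classical sums-of-squares ANOVA with one
#' between-subject factor (group) and two within-subject factors (epoch and
#' triplet type) on the per-epoch summaries. Error terms follow the standard
#' partition for this design: subjects-within-groups for the group effect;
#' the subject x epoch (within group) stratum for epoch and group x epoch;
#' the subject x triplet stratum for triplet and group x triplet; and the
#' subject x epoch x triplet stratum for the remaining interactions. Effect
#' sizes are partial eta squared, `SS_effect / (SS_effect + SS_error)` with
#' each effect's own error term. Degrees of freedom are uncorrected (with 8
#' epochs and N participants the three-way interaction has df (7, 7(N-2)));
#' Greenhouse-Geisser epsilons for the within effects are attached as the
#' `"gg_epsilon"` attribute as supplementary output.
#'
#' @param summaries Output of [aggregate_epochs()]; every participant must
#'   have all epoch x triplet cells non-missing.
#' @param dv `"median_rt_ms"` or `"mean_accuracy"`.
#' @param bf Also compute exclusion Bayes factors via [bf_model_space()] and
#'   [exclusion_bf()] and attach them as the `bf_excl` column (default
#'   `TRUE`).
#' @return A data frame with one row per effect (`Group`, `Epoch`,
#'   `Triplet`, `Group:Epoch`, `Group:Triplet`, `Epoch:Triplet`,
#'   `Group:Epoch:Triplet`) and columns `effect`, `F`, `df_num`, `df_den`,
#'   `p`, `partial_eta_sq`, and (when `bf = TRUE`) `bf_excl`.
#' @examples
#' trials <- simulate_study(group_spec("NTP", 4), group_spec("ASD", 4),
#'                          seed = 2, n_blocks = 10)
#' epochs <- aggregate_epochs(filter_rt_outliers(classify_triplets(trials)))
#' mixed_anova(epochs, "median_rt_ms", bf = FALSE)
#' @export
mixed_anova <- function(summaries, dv = "median_rt_ms", bf = TRUE) {
  d <- .anova_frame(summaries, dv)
  fit <- stats::aov(y ~ group * epoch * triplet + Error(pid / (epoch * triplet)),
                    data = d)
  s <- summary(fit)
  tab <- do.call(rbind, lapply(names(s), function(stratum) {
    df <- as.data.frame(s[[stratum]][[1L]])
    df$term <- trimws(rownames(df))
    df$stratum <- stratum
    df
  }))
  err <- tab[tab$term == "Residuals", ]
  eff <- tab[tab$term != "Residuals", ]
  eff$err_ss <- err$`Sum Sq`[match(eff$stratum, err$stratum)]
  eff$err_df <- err$Df[match(eff$stratum, err$stratum)]

  effect_map <- c(group = "Group", epoch = "Epoch", triplet = "Triplet",
                  `group:epoch` = "Group:Epoch",
                  `group:triplet` = "Group:Triplet",
                  `epoch:triplet` = "Epoch:Triplet",
                  `group:epoch:triplet` = "Group:Epoch:Triplet")
  eff$effect <- effect_map[eff$term]
  ord <- match(c("Group", "Epoch", "Triplet", "Group:Epoch", "Group:Triplet",
                 "Epoch:Triplet", "Group:Epoch:Triplet"), eff$effect)
  eff <- eff[ord, ]
  res <- data.frame(
    effect = eff$effect,
    F = eff$`F value`,
    df_num = as.integer(eff$Df),
    df_den = as.integer(eff$err_df),
    p = eff$`Pr(>F)`,
    partial_eta_sq = eff$`Sum Sq` / (eff$`Sum Sq` + eff$err_ss),
    row.names = NULL
  )
  if (bf) {
    space <- bf_model_space(summaries, dv)
    res$bf_excl <- vapply(res$effect, function(e) exclusion_bf(space, e),
                          numeric(1L))
  }
  attr(res, "gg_epsilon") <- .gg_epsilons(d)
  res
}

# Greenhouse-Geisser epsilon for each within-subject effect, from the pooled
# within-group covariance of the subjects' cell scores projected onto the
# effect's orthonormal contrast.
.gg_epsilons <- function(d) {
  E <- nlevels(d$epoch); Tt <- nlevels(d$triplet)
  d <- d[order(d$pid, d$epoch, d$triplet), ]
  Y <- matrix(d$y, ncol = E * Tt, byrow = TRUE)   # subjects x cells
  grp <- tapply(as.character(d$group), d$pid, unique)[levels(d$pid)]
  # pooled within-group covariance
  centered <- do.call(rbind, lapply(unique(grp), function(g) {
    scale(Y[grp == g, , drop = FALSE], scale = FALSE)
  }))
  S <- crossprod(centered) / (nrow(Y) - length(unique(grp)))
  hel <- function(k) {   # k x (k-1) orthonormal contrasts
    qr.Q(qr(stats::contr.helmert(k)))
  }
  one <- function(Ce, Ct) {
    C <- kronecker(Ce, Ct)   # cells ordered epoch-major, triplet-minor
    M <- t(C) %*% S %*% C
    d_f <- ncol(C)
    sum(diag(M))^2 / (d_f * sum(M^2))
  }
  ie <- diag(E); it <- diag(Tt)
  je <- matrix(1 / sqrt(E), E, 1); jt <- matrix(1 / sqrt(Tt), Tt, 1)
  c(Epoch = one(hel(E), jt),
    Triplet = one(je, hel(Tt)),
    `Epoch:Triplet` = one(hel(E), hel(Tt)))
}

#' Holm step-down adjustment of p-values
#'
#' Thin validating wrapper around `stats::p.adjust(method = "holm")`:
#' p-values are sorted ascending, the i-th smallest is multiplied by
#' `m - i + 1`, a running maximum enforces monotonicity, results are capped
#' at 1 and returned in the input order.
#'
#' @param pvals Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in the input order.
#' @export
holm_adjust <- function(pvals) {
  if (!is.numeric(pvals) || any(is.na(pvals)) ||
      any(pvals < 0 | pvals > 1)) {
    stop("p-values must be numbers in [0, 1]")
  }
  stats::p.adjust(pvals, method = "holm")
}

#' Per-epoch high- versus low-probability comparisons
#'
#' Follow-up to the epoch x triplet interaction: one paired t test per epoch
#' comparing the high- and low-probability summaries across all participants
#' (groups pooled), with the 8 p-values Holm-adjusted as one family.
#'
#' @param summaries Output of [aggregate_epochs()].
#' @param dv `"median_rt_ms"` or `"mean_accuracy"`.
#' @return A data frame with one row per epoch: `epoch`, `mean_score` (the
#'   learning score: low minus high for RT, high minus low for accuracy),
#'   `t`, `df`, `p`, `p_holm`.
#' @export
epochwise_triplet_tests <- function(summaries, dv = "median_rt_ms") {
  d <- .anova_frame(summaries, dv)
  wide <- lapply(split(d, d$epoch), function(de) {
    de <- de[order(de$pid, de$triplet), ]
    hi <- de$y[de$triplet == "HIGH"]
    lo <- de$y[de$triplet == "LOW"]
    score <- if (dv == "mean_accuracy") hi - lo else lo - hi
    n <- length(score)
    if (n < 2L) stop("need >= 2 participants")
    se <- stats::sd(score) / sqrt(n)
    t <- if (se == 0) {
      if (mean(score) == 0) 0 else sign(mean(score)) * Inf
    } else mean(score) / se
    p <- 2 * stats::pt(-abs(t), df = n - 1L)
    data.frame(epoch = unique(as.integer(as.character(de$epoch))),
               mean_score = mean(score), t = t, df = n - 1L, p = p)
  })
  out <- do.call(rbind, wide)
  out <- out[order(out$epoch), ]
  out$p_holm <- holm_adjust(out$p)
  rownames(out) <- NULL
  out
}
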