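# Independent oracles, implemented from definitional formulas only.

# Textbook sums-of-squares for the 2-group x epoch x triplet mixed design.
# Subjects are weighted equally; group sums use group sizes. Returns the
# seven effect F ratios plus dfs, computed only from cell/marginal means.
oracle_mixed_anova <- function(d) {
  # d: data.frame pid, group, epoch, triplet, y (factors, complete balanced)
  grand <- mean(d$y)
  N <- nlevels(d$pid); E <- nlevels(d$epoch); Tt <- nlevels(d$triplet)
  ngi <- table(tapply(as.character(d$group), d$pid, unique))
  n_groups <- length(ngi)

  ms <- tapply(d$y, d$pid, mean)
  SS_bs <- E * Tt * sum((ms - grand)^2)
  mg <- tapply(d$y, d$group, mean)
  SS_G <- E * Tt * sum(ngi[names(mg)] * (mg - grand)^2)
  SS_sw <- SS_bs - SS_G

  me <- tapply(d$y, d$epoch, mean)
  SS_E <- N * Tt * sum((me - grand)^2)
  mge <- tapply(d$y, list(d$group, d$epoch), mean)
  SS_GE <- Tt * sum(as.vector(ngi[rownames(mge)]) * (mge - grand)^2) -
    SS_G - SS_E
  mse <- tapply(d$y, list(d$pid, d$epoch), mean)
  SS_Es <- Tt * sum((mse - grand)^2) - SS_bs - SS_E - SS_GE

  mt <- tapply(d$y, d$triplet, mean)
  SS_T <- N * E * sum((mt - grand)^2)
  mgt <- tapply(d$y, list(d$group, d$triplet), mean)
  SS_GT <- E * sum(as.vector(ngi[rownames(mgt)]) * (mgt - grand)^2) -
    SS_G - SS_T
  mst <- tapply(d$y, list(d$pid, d$triplet), mean)
  SS_Ts <- E * sum((mst - grand)^2) - SS_bs - SS_T - SS_GT

  met <- tapply(d$y, list(d$epoch, d$triplet), mean)
  SS_ET <- N * sum((met - grand)^2) - SS_E - SS_T
  mget <- tapply(d$y, list(d$group, d$epoch, d$triplet), mean)
  SS_cells <- sum(array(as.vector(ngi[dimnames(mget)[[1L]]]),
                        dim = dim(mget)) * (mget - grand)^2)
  SS_GET <- SS_cells - SS_G - SS_E - SS_T - SS_GE - SS_GT - SS_ET
  SS_tot <- sum((d$y - grand)^2)
  SS_ETs <- SS_tot - SS_cells - SS_sw - SS_Es - SS_Ts

  df_sw <- N - n_groups
  dfs <- list(
    Group = c(n_groups - 1, df_sw, SS_G, SS_sw),
    Epoch = c(E - 1, (E - 1) * df_sw, SS_E, SS_Es),
    Triplet = c(Tt - 1, (Tt - 1) * df_sw, SS_T, SS_Ts),
    `Group:Epoch` = c((n_groups - 1) * (E - 1), (E - 1) * df_sw, SS_GE, SS_Es),
    `Group:Triplet` = c((n_groups - 1) * (Tt - 1), (Tt - 1) * df_sw,
                        SS_GT, SS_Ts),
    `Epoch:Triplet` = c((E - 1) * (Tt - 1), (E - 1) * (Tt - 1) * df_sw,
                        SS_ET, SS_ETs),
    `Group:Epoch:Triplet` = c((n_groups - 1) * (E - 1) * (Tt - 1),
                              (E - 1) * (Tt - 1) * df_sw, SS_GET, SS_ETs)
  )
  out <- do.call(rbind, lapply(names(dfs), function(nm) {
    v <- dfs[[nm]]
    data.frame(effect = nm, df_num = v[1], df_den = v[2], ss = v[3],
               ss_err = v[4],
               F = (v[3] / v[1]) / (v[4] / v[2]))
  }))
  rownames(out) <- NULL
  out
}

# Brute-force Mann-Whitney U: count pairwise wins, ties as one half.
oracle_u <- function(x, y) {
  u1 <- 0
  for (xi in x) for (yi in y) {
    u1 <- u1 + (xi > yi) + 0.5 * (xi == yi)
  }
  min(u1, length(x) * length(y) - u1)
}

# Brute-force boxplot outlier flags (type-7 quartiles by direct
# interpolation on the sorted sample).
oracle_box_outliers <- function(rt, k = 1.5) {
  s <- sort(rt)
  n <- length(s)
  qt <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
  }
  q1 <- qt(0.25); q3 <- qt(0.75); iqd <- q3 - q1
  rt < q1 - k * iqd | rt > q3 + k * iqd
}

# Random complete balanced epoch-summary table for ANOVA equivalence tests.
random_summary_table <- function(n1, n2, E, seed, sd_subj = 20, sd_noise = 15) {
  set.seed(seed)
  pids <- sprintf("s%02d", seq_len(n1 + n2))
  grp <- rep(c("NTP", "ASD"), c(n1, n2))
  g <- expand.grid(participant_id = pids, epoch = seq_len(E),
                   triplet_type = c("HIGH", "LOW"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$group <- grp[match(g$participant_id, pids)]
  subj_int <- stats::rnorm(n1 + n2, 0, sd_subj)
  g$median_rt_ms <- 400 + subj_int[match(g$participant_id, pids)] +
    stats::rnorm(nrow(g), 0, sd_noise)
  g$mean_accuracy <- pmin(1, pmax(0, 0.9 + stats::rnorm(nrow(g), 0, 0.03)))
  g$n_trials <- 50L
  g$n_rt_trials <- 45L
  g
}

# Long factor frame matching .anova_frame's layout, for the oracle.
as_oracle_frame <- function(summaries, dv = "median_rt_ms") {
  data.frame(pid = factor(summaries$participant_id),
             group = factor(summaries$group),
             epoch = factor(summaries$epoch),
             triplet = factor(summaries$triplet_type),
             y = summaries[[dv]])
}
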