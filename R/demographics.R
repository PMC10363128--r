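#' Two-sample t test from summary statistics
#'
#' Pooled-variance independent-samples t statistic computed from group
#' means, standard deviations, and sizes, as used for demographic tables
#' where only summaries are printed. Sign convention: group 1 minus group 2.
#'
#' @param m1,sd1,n1 Mean, standard deviation, and size of group 1.
#' @param m2,sd2,n2 Mean, standard deviation, and size of group 2.
#' @return A list with `t`, `df` (`n1 + n2 - 2`), and the two-sided `p`.
#' @examples
#' # autism-spectrum quotient: 15.20 (5.73), n=20 vs 31.09 (6.62), n=22
#' two_sample_t_from_summary(15.20, 5.73, 20, 31.09, 6.62, 22)
#' @export
two_sample_t_from_summary <- function(m1, sd1, n1, m2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2")
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be positive")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-square for a 2x2 table
#'
#' Chi-square test of independence without continuity correction (df = 1),
#' for contingency tables such as sex by group.
#'
#' @param a,b,c,d Cell counts, row-wise: `a b` on the first row, `c d` on
#'   the second.
#' @return A list with `chi_sq`, `df` (1), and `p`.
#' @examples
#' chi2_2x2(6, 14, 4, 18)  # females/males by group
#' @export
chi2_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be nonnegative integers")
  }
  m <- matrix(counts, nrow = 2L, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("all table margins must be positive")
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(chi_sq = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Mann-Whitney U statistic
#'
#' Rank-sum comparison of two independent samples with midrank tie
#' handling. Returns the conventional `U = min(U1, U2)`, where
#' `U1 + U2 = n1 * n2`.
#'
#' @param x,y Nonempty numeric samples.
#' @return A list with `u`, `u1` (wins of `x`, counting ties as half), `u2`,
#'   and the two-sided `p` from `stats::wilcox.test` (normal approximation
#'   in the presence of ties).
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("samples must be nonempty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  p <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                           correct = FALSE)$p.value)
  list(u = min(u1, u2), u1 = u1, u2 = u2, p = p)
}
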