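---
title: "Methods: simulating and analyzing the alternating serial reaction time task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing the alternating serial reaction time task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asrtlab)
```

## The task and its probability structure

The alternating serial reaction time (ASRT) task is a four-choice reaction
time task in which a probabilistic regularity is hidden from the
participant. Stimulus positions alternate between *pattern* trials, which
visit a fixed four-element cycle of the screen positions (for example
1, 2, 4, 3), and *random* trials drawn uniformly from the four positions.
Each 85-trial block starts with five uniformly random warm-up trials,
followed by the eight-element alternating unit repeated ten times, the
pattern restarting at the cycle's first element in every block.

The regularity lives at the level of *triplets* — runs of three consecutive
trials. A triplet is classified by its first and third elements alone: it is
**high-probability** when the third element is the pattern successor of the
first, **low-probability** otherwise. Of the $4^3 = 64$ ordered triplets, 16
are high-probability (4 pattern transitions $\times$ 4 middle elements) and
48 are low-probability, for every one of the 24 possible cycles:

```{r}
triplet_census(asrt_pattern(c(1, 2, 4, 3)))
```

Because the cycle is a derangement-free permutation cycle (no position maps
to itself), a high-probability triplet can never have identical first and
third elements; trills (2-1-2) and repetitions (2-2-2) are therefore always
low-probability, and flagging them takes precedence over the high/low split
without ever hiding a high-probability triplet.

Over the generative process, pattern-ending triplets
(pattern–random–pattern) are high-probability with certainty, while
random-ending triplets (random–pattern–random) are high-probability with
probability 1/4. With the two trial types in equal shares among
classifiable trials, high-probability triplets occur with probability
$1/2 \cdot 1 + 1/2 \cdot 1/4 = 0.625$: 50% of classifiable trials are
pattern-ending high, 12.5% random-ending high, and per unique triplet the
occurrence rates are $0.625/16 \approx 4\%$ and $0.375/48 \approx 0.8\%$.

```{r}
unlist(analytic_occurrence(asrt_pattern(c(1, 2, 4, 3))))
```

### Why the sliding window starts at trial 8

The three-trial window never crosses a block boundary, since blocks are
separated by feedback and rest screens, and it also never reaches into the
five warm-up trials. The latter is a deliberate choice: if warm-up trials
were allowed as window *predecessors*, the first pattern trial of each block
(trial 6) would end a triplet whose first element is uniformly random, and
would be high-probability only with probability 1/4 rather than with
certainty. Generated sessions would then show an overall high-probability
rate of about 61.5% instead of the exact 62.5% the task is designed around.
Excluding warm-up predecessors makes each block contribute 78 classifiable
trials — 39 pattern-ending (all high) and 39 random-ending (high with
probability 1/4) — which reproduces the exact fractions
$48.75/78 = 0.625$, $39/78 = 0.5$ and $9.75/78 = 0.125$. Trials 6 and 7
are flagged `no_window` and excluded, alongside the warm-up trials
themselves.

Whether one fixed cycle was used for all participants or cycles were
counterbalanced is a degree of freedom of the design; the simulator
defaults to an independent uniformly random cycle per participant, and the
preprocessing results are invariant to relabeling positions (asserted in
the test suite), so this choice cannot leak into the group statistics.

## The synthetic participant model

The simulator exists so that every downstream stage is testable without
access to archived raw data. It combines three standard pieces of RT
phenomenology:

* a **power-law practice curve** over blocks,
  $baseline + amp \cdot b^{-decay}$;
* a **saturating learning advantage** for trials ending a high-probability
  triplet, $\Delta(e) = asym \cdot (1 - e^{-rate \cdot e})$ with $e$ the
  epoch (five consecutive blocks);
* **multiplicative lognormal trial noise**, $RT = \max(floor,\ \mu \cdot
  e^{\varepsilon})$, $\varepsilon \sim N(0, \sigma)$.

First-response accuracy mirrors the RT advantage: the error probability is
`base_error` minus a saturating reduction on high-probability trials,
clipped to $[0.001, 0.5]$. The task is self-paced, so an incorrect first
response is followed by guessing until correct; the number of extra
attempts is geometric with success probability 3/4. First-response RT is
logged for every trial regardless of correctness; the restriction to
correct responses happens downstream, in aggregation.

Defaults (per-participant values are drawn from normal distributions
truncated to valid ranges):

| parameter | mean | between-participant SD | units |
|---|---|---|---|
| `baseline_rt_ms` | 380 | 40 | ms |
| `practice_amp_ms` | 120 | 30 | ms |
| `practice_decay` | 0.30 | 0.08 | — |
| `learn_asymptote_ms` | 30 | 10 | ms |
| `learn_rate` | 0.50 | 0.15 | per epoch |
| `noise_sigma` | 0.18 | 0.03 | log-ms |
| `base_error` | 0.08 | 0.02 | probability |
| `error_reduction` | 0.04 | 0.015 | probability |
| `floor_rt_ms` | 150 | 0 | ms |

These values were chosen once, as what a practitioner would call a
realistic ASRT data set: first-epoch median RTs around 450–500 ms decaying
toward 400 ms, learning scores growing toward roughly 30 ms (the order of
magnitude typical of adult ASRT learning curves), accuracies around 92%,
and — crucially — *identical distributions in both groups*, because the
study design the package emulates found no group differences in learning.
Group differences are opt-in through `group_spec(means = ...)`.

What the simulator deliberately does **not** emulate: sequential RT
autocorrelation, post-error slowing, fatigue or vigilance dips, explicit
strategy shifts, and any cognitive-process mechanism (prediction-error
weighting, volatility estimation). Passing tests therefore show that the
*pipeline* is correct and calibrated under a plausible data-generating
process, not that real data obey this response model.

## Preprocessing

1. **Classification**: each trial is labeled in a sliding window by the
   triplet it completes (`HIGH`, `LOW`, `TRILL_OR_REP`, `UNCLASSIFIABLE`).
2. **Trill/repetition exclusion**: endpoints with identical first and third
   elements are dropped (pre-existing response tendencies make them fast
   regardless of learning).
3. **RT outlier removal**: the boxplot rule with $k = 1.5$ inter-quartile
   distances, applied per participant over the trials still included, in a
   single pass (no re-iteration on the filtered sample). Quartiles are
   computed per participant — rather than pooled across the sample — so
   that slow participants are not wholesale flagged as outliers; and over
   the union of high- and low-probability trials, matching a single global
   exclusion rate per participant.
4. **Aggregation**: per participant × epoch × triplet type, median RT over
   included *correct* first responses (standard ASRT practice; error-trial
   RTs measure something else), mean accuracy over all included trials.
   Even-count medians are the midpoint of the central pair. Empty cells
   stay missing and are never imputed; the ANOVA layer rejects participants
   with missing cells by name.

The per-epoch **learning score** is the low-minus-high median RT
difference (positive = learning) and the high-minus-low accuracy
difference.

## Inference

### Mixed-design ANOVA

The central test is a 2 (group, between) × 8 (epoch, within) × 2 (triplet
type, within) classical sums-of-squares ANOVA on the epoch summaries, with
the standard error strata: subjects-within-groups for the group effect, and
the subject × (within-factor) interactions for each within-subject effect
family. Effect sizes are partial eta squared,
$\eta_p^2 = SS_{effect} / (SS_{effect} + SS_{error})$. Degrees of freedom
are reported uncorrected — with 8 epochs and $N$ subjects the three-way
interaction has $(7,\ 7(N-2))$, i.e. $(7, 280)$ at $N = 42$ —
and Greenhouse–Geisser epsilons are attached as supplementary output
rather than used to correct the tests. With unequal group sizes the
sequential (weighted-means) decomposition is used; within-subject factors
are balanced within every subject, so the within strata are orthogonal to
group size.

Follow-up per-epoch high-versus-low paired t tests pool the groups (the
follow-up family belongs to the epoch × triplet interaction, not to group
contrasts) and are Holm-corrected as one family of 8.

### Exclusion Bayes factors

To quantify evidence *for the null* — the point of the design — the package
computes exclusion Bayes factors across matched models. The model space is
every sub-model of the full three-way factorial that respects marginality
(an interaction enters only with all its constituent terms): 19 models
including the null. Each model is fit by least squares with fixed subject
blocking and scored by BIC; $BF_{model,null} =
\exp((BIC_{null} - BIC_{model})/2)$, the unit-information-prior
approximation. With equal prior model probabilities, the exclusion BF of an
effect compares the posterior mass of the models that contain it (but no
interaction built on it) against the same models with the effect removed.
Values above 3 are read as substantial evidence for the effect's absence,
below 1/3 as substantial evidence for its presence.

Two knowing divergences from a JZS-prior Bayesian ANOVA, accepted for
determinism and desk-scale runtime: the BIC approximation uses a different
prior, so numerical BF values will differ from JASP-style outputs even in
direction-agreeing cases; and because subjects are nested in groups, fixed
subject blocking absorbs the group *main* effect, whose exclusion BF is
therefore identically 1 (all its interactions, which carry the scientific
questions here, are unaffected). Random slopes are not separately
estimable under the BIC scheme and are not modeled.

### Demographic-table helpers

`two_sample_t_from_summary()` (pooled variance — the convention that
reproduces $df = n_1 + n_2 - 2$ from printed group summaries),
`chi2_2x2()` (Pearson, no continuity correction), and `mann_whitney_u()`
(midrank ties, $U = \min(U_1, U_2)$) cover the tests used for demographic
comparisons when only summary statistics or small raw vectors are
available.

## Numerical and design choices

* **Determinism**: every stochastic entry point takes a seed;
  `simulate_study()` derives independent sub-seeds per participant for
  parameters, cycle, stimulus stream, and responses, so adding a
  participant does not perturb the others.
* **Ties and degenerate inputs**: zero-IQD samples flag no outliers (the
  closed range contains every value); paired tests on identical cells
  return $t = 0$, $p = 1$; empty cells propagate missingness; single-epoch
  tables are rejected by the analysis stage with a stage-named error.
* **Problem sizes**: the test suite's Monte-Carlo checks run at reduced
  scale chosen once — null calibration with 500 replications of 10-block
  sessions at $n = 20/22$ (type-I rate of the group × triplet test within
  Monte-Carlo error of 5%, median exclusion BF above 1), and parameter
  recovery of a 30 ms asymptote from 20 replications of full 40-block
  sessions at $n = 20$ (mean epoch-8 learning score within ±5 ms).
* **Known limitations**: BIC-based BFs are approximations, not JZS values;
  the weighted-means ANOVA decomposition differs from Type-III marginal
  tests when group sizes are unequal *and* group interactions are nonzero;
  the simulator's response model is phenomenological, not mechanistic.

## End-to-end use

```{r, eval = FALSE}
cfg <- study_config(group_spec("NTP", 20), group_spec("ASD", 22), seed = 1)
out <- run_pipeline(cfg, "asrt-out")
out$results$median_rt_ms$anova
```

The bundle contains the trial-level CSV, the epoch-summary CSV, an
exclusion report (both readings of the outlier rate: as a share of all
trials and of classifiable trials), a results JSON validating against the
schema in `inst/schema/`, and a learning-curve figure with standard-error
bands and the mid-session break marked after epoch 4.
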