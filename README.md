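# asrtlab

Implicit statistical learning — picking up the probability structure of the
environment without intending to — is commonly measured with the
**alternating serial reaction time (ASRT) task**: a four-choice RT task in
which every other stimulus position follows a hidden four-element cycle and
the rest are uniformly random. The alternation makes some runs of three
trials ("triplets") frequent and predictable: a triplet is
*high-probability* when its third position is the cycle successor of its
first. Out of 64 ordered triplets, 16 are high-probability and occur with
62.5% overall probability; learning shows up as faster, more accurate
responses on trials completing high-probability triplets, and is summarized
by the per-epoch **learning score**

&nbsp;&nbsp;&nbsp;&nbsp;*score(e) = median RT(low, e) − median RT(high, e)*.

`asrtlab` is an R package providing the full research pipeline around this
design, for studies comparing two groups (e.g. neurotypical vs. autistic
adults) across practice:

* **Task structure** — exact generators of the alternating stimulus streams
  (40 blocks × 85 trials: 5 warm-up + 10 repetitions of the eight-element
  unit) and the analytic triplet combinatorics and occurrence
  probabilities, by enumeration.
* **Synthetic participants** — a response model with a power-law practice
  curve, a saturating high-vs-low advantage, lognormal trial noise, and
  self-paced guessing after errors, so every downstream stage is testable
  without raw behavioral data.
* **Preprocessing** — sliding-window triplet classification,
  trill/repetition exclusion, per-participant 1.5-IQD boxplot outlier
  removal, per-epoch median RT / mean accuracy, learning scores, and an
  itemized exclusion report.
* **Inference** — 2 × 8 × 2 mixed-design repeated-measures ANOVA with
  partial η², Holm-corrected per-epoch follow-ups, BIC-approximated
  **exclusion Bayes factors** across the 19 marginality-respecting models
  (evidence *for* null effects), and demographic-table helpers (pooled t
  from summary statistics, Pearson χ², Mann–Whitney U).
* **Orchestration** — a one-call `run_pipeline()` producing the trial CSV,
  epoch CSV, exclusion JSON, results JSON (schema in `inst/schema/`), and a
  learning-curve figure, plus a thin command-line front end in
  `inst/scripts/asrt-lab.R`.

## Worked example

```r
library(asrtlab)

trials     <- simulate_study(group_spec("NTP", 10), group_spec("ASD", 10),
                             seed = 1)                  # 20 x 3400 trials
classified <- filter_rt_outliers(classify_triplets(trials))
epochs     <- aggregate_epochs(classified)
mixed_anova(epochs, "median_rt_ms")
```

```
               effect       F df_num df_den        p partial_eta_sq  bf_excl
1               Group   0.558      1     18 4.65e-01         0.0300 1.00e+00
2               Epoch 130.860      7    126 1.16e-54         0.8791 7.18e-93
3             Triplet 134.811      1     18 8.56e-10         0.8822 2.78e-58
4         Group:Epoch   0.675      7    126 6.93e-01         0.0362 3.77e+07
5       Group:Triplet   0.206      1     18 6.56e-01         0.0113 1.29e+01
6       Epoch:Triplet   7.650      7    126 1.10e-07         0.2982 2.08e+01
7 Group:Epoch:Triplet   0.931      7    126 4.85e-01         0.0492 6.07e+07
```

Reading the table: responses speed up with practice (Epoch) and are faster
on high-probability triplets (Triplet, *F*(1,18) = 134.8, η²p = 0.88, with
an exclusion Bayes factor of 2.8 × 10⁻⁵⁸ — overwhelming evidence *for* the
effect), while the Group rows show what a two-group null looks like:
non-significant *F*s and exclusion BFs above 1, favouring models without
group terms. (The Group main effect's BF is identically 1 by construction:
subject blocking absorbs it; see the methods vignette.) The per-epoch mean
learning scores from the same run,

```
   1    2    3    4    5    6    7    8
 9.4 15.8 20.3 27.3 27.0 27.2 24.5 25.9
```

rise from ~9 ms to a ~26–30 ms plateau — the gradual emergence of
statistical learning. `exclusion_report(classified)` itemizes the dropped
trials (here 1.12% RT outliers).

See `vignettes/asrt-methods.Rmd` for the response model, the exact
combinatorics (including why classification windows start at trial 8), the
ANOVA error strata, and the matched-models Bayes factor scheme.

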