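Package: asrtlab
Title: Simulation and Analysis Pipeline for the Alternating Serial Reaction
    Time Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying implicit statistical learning with the
    alternating serial reaction time (ASRT) task. Generates stimulus streams
    with the task's alternating pattern/random structure, exposes the exact
    triplet-probability combinatorics, simulates synthetic participants with a
    practice curve and a gradually emerging high- versus low-probability
    triplet advantage, implements the standard preprocessing chain (sliding
    window triplet classification, trill and repetition exclusion,
    interquartile-distance outlier removal, per-epoch median reaction time and
    mean accuracy), and provides the group-level inferential battery: a
    mixed-design repeated-measures ANOVA with partial eta squared,
    Holm-corrected follow-up comparisons, BIC-based exclusion Bayes factors
    across matched models, and demographic-table helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
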