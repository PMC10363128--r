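#' Study configuration
#'
#' Bundles everything one end-to-end run needs: the two [group_spec()]s, the
#' task parameters, the analysis options, and the master seed. A plain-text
#' YAML equivalent can be loaded with [read_study_config()].
#'
#' @param ntp,asd [group_spec()] objects.
#' @param seed Master integer seed (mandatory for simulation runs).
#' @param n_blocks Blocks per participant (default 40).
#' @param blocks_per_epoch Blocks per epoch (default 5).
#' @param iqd_k Outlier whisker multiplier (default 1.5).
#' @param dvs Dependent variables to analyze.
#' @param bayes Compute exclusion Bayes factors (default `TRUE`).
#' @return A list of class `study_config`.
#' @export
study_config <- function(ntp = group_spec("NTP"), asd = group_spec("ASD"),
                         seed = 1L, n_blocks = 40L, blocks_per_epoch = 5L,
                         iqd_k = 1.5,
                         dvs = c("median_rt_ms", "mean_accuracy"),
                         bayes = TRUE) {
  stopifnot(inherits(ntp, "group_spec"), inherits(asd, "group_spec"))
  if (is.null(seed)) stop("a seed is mandatory for simulation runs")
  dvs <- match.arg(dvs, c("median_rt_ms", "mean_accuracy"),
                   several.ok = TRUE)
  structure(list(ntp = ntp, asd = asd, seed = as.integer(seed),
                 n_blocks = as.integer(n_blocks),
                 blocks_per_epoch = as.integer(blocks_per_epoch),
                 iqd_k = iqd_k, dvs = dvs, bayes = isTRUE(bayes)),
            class = "study_config")
}

#' Load a study configuration from YAML
#'
#' Schema: top-level keys `seed`, and optionally `n_blocks`,
#' `blocks_per_epoch`, `iqd_k`, `dvs`, `bayes`, and `groups`. `groups` maps
#' the labels `NTP` and `ASD` to lists with optional `n_participants`,
#' `means`, and `sds` entries (see [group_spec()]).
#'
#' @param path Path to the YAML file.
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  mk_spec <- function(label) {
    g <- cfg$groups[[label]]
    group_spec(label,
               n_participants = g$n_participants,
               means = if (is.null(g$means)) list() else g$means,
               sds = if (is.null(g$sds)) list() else g$sds)
  }
  args <- list(ntp = mk_spec("NTP"), asd = mk_spec("ASD"), seed = cfg$seed)
  for (k in c("n_blocks", "blocks_per_epoch", "iqd_k", "dvs", "bayes")) {
    if (!is.null(cfg[[k]])) args[[k]] <- cfg[[k]]
  }
  do.call(study_config, args)
}

#' Run the full simulate-preprocess-analyze pipeline
#'
#' Executes the stages in order -- simulate the study, classify triplets,
#' flag RT outliers, aggregate epochs, run the frequentist and Bayesian
#' analyses -- and writes the report bundle: `trials.csv`, `epochs.csv`,
#' `exclusions.json`, `results.json`, and `learning_curves.pdf` (group-mean
#' high/low RT per epoch and per-epoch learning scores with standard-error
#' bands, with the mid-session break marked after epoch 4). Each stage is
#' logged to stderr with the seed and key parameters; a failing stage aborts
#' with an error naming the stage, and outputs written by earlier stages are
#' retained.
#'
#' @param config A [study_config()].
#' @param out_dir Output directory (created if missing).
#' @param figure Write the learning-curve figure (default `TRUE`).
#' @return Invisibly, a list with the trial table, epoch summaries,
#'   exclusion report, per-dv analysis results, and the output paths.
#' @export
run_pipeline <- function(config, out_dir, figure = TRUE) {
  stopifnot(inherits(config, "study_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    message(sprintf("[asrtlab] stage %-10s seed=%d", name, config$seed))
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  paths <- list(trials = file.path(out_dir, "trials.csv"),
                epochs = file.path(out_dir, "epochs.csv"),
                exclusions = file.path(out_dir, "exclusions.json"),
                results = file.path(out_dir, "results.json"),
                figure = file.path(out_dir, "learning_curves.pdf"))

  trials <- stage("simulate", {
    tr <- simulate_study(config$ntp, config$asd, seed = config$seed,
                         n_blocks = config$n_blocks,
                         blocks_per_epoch = config$blocks_per_epoch)
    write_trials_csv(tr, paths$trials)
    tr
  })
  prep <- stage("preprocess", {
    cl <- classify_triplets(trials)
    cl <- filter_rt_outliers(cl, k = config$iqd_k)
    rep <- exclusion_report(cl)
    jsonlite::write_json(rep, paths$exclusions, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    epochs <- aggregate_epochs(cl, blocks_per_epoch = config$blocks_per_epoch)
    write_epochs_csv(epochs, paths$epochs)
    list(classified = cl, epochs = epochs, report = rep)
  })
  results <- stage("analyze", {
    res <- lapply(config$dvs, function(dv) {
      anova_tab <- mixed_anova(prep$epochs, dv, bf = config$bayes)
      list(dv = dv,
           anova = anova_tab,
           gg_epsilon = as.list(attr(anova_tab, "gg_epsilon")),
           epochwise = epochwise_triplet_tests(prep$epochs, dv))
    })
    names(res) <- config$dvs
    bundle <- list(
      seed = config$seed,
      n_blocks = config$n_blocks,
      blocks_per_epoch = config$blocks_per_epoch,
      iqd_k = config$iqd_k,
      n_participants = list(NTP = config$ntp$n_participants,
                            ASD = config$asd$n_participants),
      analyses = res
    )
    jsonlite::write_json(bundle, paths$results, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, dataframe = "rows")
    res
  })
  if (figure) {
    stage("figure", {
      p <- plot_learning_curves(prep$epochs,
                                break_after_epoch =
                                  session_metadata()$break_after_epoch)
      ggplot2::ggsave(paths$figure, p, width = 9, height = 6)
    })
  }
  invisible(list(trials = trials, epochs = prep$epochs,
                 exclusions = prep$report, results = results,
                 paths = paths))
}

#' Learning-curve figure
#'
#' Two-panel summary per group: group-mean median RT per epoch for high- and
#' low-probability triplets (the gap between the lines is the magnitude of
#' statistical learning), and the per-epoch mean RT learning score. Ribbons
#' show the standard error of the mean across participants within group; a
#' dashed vertical line marks the mid-session break.
#'
#' @param summaries Output of [aggregate_epochs()].
#' @param break_after_epoch Epoch after which the break marker is drawn
#'   (`NULL` for none).
#' @return A ggplot object.
#' @export
plot_learning_curves <- function(summaries, break_after_epoch = 4L) {
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  agg <- stats::aggregate(median_rt_ms ~ group + epoch + triplet_type,
                          data = summaries, FUN = mean)
  agg$sem <- stats::aggregate(median_rt_ms ~ group + epoch + triplet_type,
                              data = summaries, FUN = sem)$median_rt_ms
  scores <- learning_scores(summaries)
  sc <- stats::aggregate(rt_score_ms ~ group + epoch, data = scores,
                         FUN = mean)
  sc$sem <- stats::aggregate(rt_score_ms ~ group + epoch, data = scores,
                             FUN = sem)$rt_score_ms
  sc$triplet_type <- "learning score"
  agg$panel <- "median RT (ms)"
  sc$panel <- "RT learning score (ms)"
  names(sc)[names(sc) == "rt_score_ms"] <- "median_rt_ms"
  both <- rbind(agg[, c("group", "epoch", "triplet_type", "median_rt_ms",
                        "sem", "panel")],
                sc[, c("group", "epoch", "triplet_type", "median_rt_ms",
                       "sem", "panel")])
  p <- ggplot2::ggplot(
    both,
    ggplot2::aes(x = .data$epoch, y = .data$median_rt_ms,
                 colour = .data$triplet_type, fill = .data$triplet_type)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$median_rt_ms - .data$sem,
                                      ymax = .data$median_rt_ms + .data$sem),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::facet_grid(panel ~ group, scales = "free_y") +
    ggplot2::labs(x = "Epoch (5 blocks)", y = NULL, colour = "Triplet",
                  fill = "Triplet") +
    ggplot2::theme_minimal()
  if (!is.null(break_after_epoch)) {
    p <- p + ggplot2::geom_vline(xintercept = break_after_epoch + 0.5,
                                 linetype = "dashed", colour = "grey40")
  }
  p
}
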