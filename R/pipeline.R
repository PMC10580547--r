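# End-to-end orchestration: simulate -> preprocess/extract -> reduce -> axis
# search -> group statistics, with a serializable run report. One global seed
# fans out to per-stage seeds by fixed offsets so stages can be re-run alone.

#' Pipeline run configuration
#'
#' @param spec A [cohort_spec()].
#' @param effect An [effect_model()].
#' @param param_cfg A [param_config()].
#' @param ga_cfg A [ga_config()].
#' @param prune_threshold Correlation-pruning threshold.
#' @param outlier_mode `"winsorize"` or `"drop"`.
#' @param seed Global seed; the cohort uses `seed`, the GA `seed + 1000`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(spec = cohort_spec(), effect = effect_model(),
                       param_cfg = param_config(),
                       ga_cfg = ga_config(epochs = 2000L),
                       prune_threshold = 0.9,
                       outlier_mode = c("winsorize", "drop"), seed = 1L) {
  outlier_mode <- match.arg(outlier_mode)
  seed <- as.integer(seed)
  spec$seed <- seed
  ga_cfg$seed <- seed + 1000L
  structure(list(spec = spec, effect = effect, param_cfg = param_cfg,
                 ga_cfg = ga_cfg, prune_threshold = prune_threshold,
                 outlier_mode = outlier_mode, seed = seed),
            class = "run_config")
}

#' Run the full signal-to-biomarker pipeline
#'
#' Simulates raw cohort recordings, preprocesses and extracts the 324-column
#' per-trial feature table, handles outliers and averages trials, prunes
#' correlated features, runs the LDA-value estimation chain, and computes the
#' group statistics (young-vs-elderly screen with tallies, pairwise group
#' tests on the LDA-value, Pearson age correlation). Deterministic given the
#' config seed.
#'
#' @param config A [run_config()].
#' @return An object of class `run_report`: stage counts, final separability,
#'   Pearson r, and the stage outputs (`lda`, `stats`, `features`).
#' @export
run_full_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  cohort <- simulate_cohort_signals(config$spec, config$effect)
  trial_df <- extract_feature_matrix(cohort, config$param_cfg)
  n_extracted <- ncol(trial_df) - 4L
  trial_df <- handle_outliers(trial_df, config$outlier_mode)
  flags <- attr(trial_df, "flags")
  fs <- average_trials(trial_df)
  pruned <- prune_correlated(fs, config$prune_threshold)
  report <- attr(pruned, "report")
  lda <- estimate_lda_value(pruned, config$ga_cfg)
  # screen the surviving (pruned) features, as the study screens its
  # post-reduction set; constant columns are gone at this point
  screen <- young_elderly_test(pruned)
  tally <- tally_significant(screen)
  pair <- pairwise_group_test(lda$lda_values, lda$groups)
  corr <- age_correlation(lda$lda_values, lda$ages)
  structure(list(
    counts = list(participants = length(cohort$participants),
                  features_extracted = n_extracted,
                  outliers_flagged = nrow(flags),
                  features_after_pruning = ncol(pruned$x),
                  relevant_features = sum(lda$relevant_mask),
                  significant_young_elderly = sum(screen$significant)),
    ez_final = lda$ez_best, pearson_r = corr$r, pearson_p = corr$p_value,
    config = config, lda = lda,
    stats = list(screen = screen, tally = tally, pairwise = pair,
                 correlation = corr),
    features = pruned, prune_report = report, outlier_flags = flags),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  c0 <- x$counts
  cat("<run_report>\n",
      "  participants:            ", c0$participants, "\n",
      "  features extracted:      ", c0$features_extracted, "\n",
      "  outlier values flagged:  ", c0$outliers_flagged, "\n",
      "  features after pruning:  ", c0$features_after_pruning, "\n",
      "  relevant features:       ", c0$relevant_features, "\n",
      "  young/elderly sig.:      ", c0$significant_young_elderly, "\n",
      "  final E_z:               ", format(x$ez_final, digits = 6), "\n",
      "  Pearson r (age):         ", format(x$pearson_r, digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' Write a run report to disk
#'
#' Always writes JSON; optionally a human-readable text summary including the
#' seven tally views and the group-mean LDA-value-vs-age table.
#'
#' @param report A `run_report`.
#' @param path Output path without extension; `<path>.json` (and
#'   `<path>.txt`) are written.
#' @param summary Also write the text summary.
#' @return Invisibly, the JSON path.
#' @export
write_report <- function(report, path, summary = TRUE) {
  stopifnot(inherits(report, "run_report"))
  payload <- list(
    counts = report$counts,
    ez_final = report$ez_final,
    pearson_r = report$pearson_r,
    pearson_p = report$pearson_p,
    seed = report$config$seed,
    ga = report$config$ga_cfg[c("epochs", "s", "xi", "p_mutation",
                                "p_crossover", "relevance_threshold")],
    lda_values = data.frame(participant_id = report$lda$ids,
                            age = report$lda$ages,
                            group = report$lda$groups,
                            lda_value = report$lda$lda_values),
    best_axis = report$lda$best_axis,
    relevant_features = names(which(report$lda$relevant_mask)),
    tally = report$stats$tally,
    pairwise_p = report$stats$pairwise$p,
    kruskal_p = report$stats$pairwise$kruskal_p)
  json <- paste0(path, ".json")
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  if (summary) {
    txt <- paste0(path, ".txt")
    con <- file(txt, "w")
    on.exit(close(con))
    writeLines(utils::capture.output(print(report)), con)
    t0 <- report$stats$tally
    writeLines("\nTally of significant young/elderly features:", con)
    for (nm in c("per_feature", "per_param_group",
                 "per_param_group_proportion", "per_task", "per_sensor",
                 "per_sensor_type", "per_imu")) {
      writeLines(paste0("  ", nm, ": ",
                        paste(names(t0[[nm]]), format(t0[[nm]], digits = 3),
                              sep = "=", collapse = " ")), con)
    }
    gm <- tapply(report$lda$lda_values, report$lda$groups, mean)
    ga <- tapply(report$lda$ages, report$lda$groups, mean)
    writeLines("\nGroup-mean LDA-value vs age:", con)
    for (g in names(gm)) {
      writeLines(sprintf("  group %s: age %5.1f  lda %8.4f", g, ga[[g]],
                         gm[[g]]), con)
    }
  }
  invisible(json)
}
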