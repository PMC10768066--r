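# End-to-end orchestration: simulate -> preprocess -> model -> associate,
# writing every intermediate artifact as delimited text plus a JSON manifest,
# all reproducible from (config, seed).

#' Pipeline run configuration
#'
#' Bundles every tunable parameter of a run. Defaults are the analysis
#' defaults throughout the package: 17 participants, 6 SNR levels x 40
#' sentences, 3-MAD artifact threshold with 35/100 ms margins, 100 ms
#' smoothing, 40\% exclusion, 2 s baseline, Bonferroni family 24.
#'
#' @param seed global integer seed (fanned out to per-stage substreams).
#' @param n_participants cohort size.
#' @param design a [trial_design()] list.
#' @param config an [effect_config()] list.
#' @param prep a [prep_params()] list.
#' @param fs sampling rate (Hz).
#' @param bonferroni_m correlation-battery family size.
#' @param outdir output directory.
#' @return a named list of class `"pupilci_config"`.
#' @export
pipeline_config <- function(seed = 1, n_participants = 17,
                            design = trial_design(), config = effect_config(),
                            prep = prep_params(), fs = 120,
                            bonferroni_m = 24, outdir = tempfile("pupilci_run_")) {
  cfg <- as.list(environment())
  class(cfg) <- "pupilci_config"
  cfg
}

write_table <- function(x, dir, name) {
  utils::write.csv(x, file.path(dir, name), row.names = FALSE, na = "")
}

fit_to_list <- function(f) {
  list(family = f$family, formula = f$formula_descr, singular = f$singular,
       fixed_effects = f$fixed_effects, lrt = f$lrt, posthoc = f$posthoc)
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort, preprocesses every trial, fits the psychometric
#' models (SNR-condition, polynomial shape, accuracy, TLX, word-group
#' interaction), computes per-participant shape parameters and the
#' correlation battery, and writes all tables (`profiles.csv`, `events.csv`,
#' `trial_metrics.csv`, `condition_traces.csv`, `cell_means.csv`,
#' `shape_params.csv`, `correlation_table.csv`, `moderated_regressions.csv`,
#' `model_summaries.json`) plus `manifest.json` (config, software version,
#' per-stage row counts and the excluded-trial fraction) to `cfg$outdir`.
#'
#' @param cfg a [pipeline_config()] list.
#' @return (invisibly) a list with all in-memory results and `outdir`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pupilci_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)

  cohort <- simulate_cohort(cfg$n_participants, cfg$design, cfg$config,
                            seed = cfg$seed, fs = cfg$fs)
  write_table(cohort$profiles, cfg$outdir, "profiles.csv")
  write_table(cohort$events, cfg$outdir, "events.csv")

  prep <- preprocess_cohort(cohort$samples, cohort$events, cfg$prep, fs = cfg$fs)
  write_table(prep$trial_metrics, cfg$outdir, "trial_metrics.csv")
  write_table(prep$condition_traces, cfg$outdir, "condition_traces.csv")
  write_table(prep$cell_means, cfg$outdir, "cell_means.csv")

  cond_fit <- fit_condition_model(prep$cell_means)
  poly_fit <- fit_polynomial_model(prep$cell_means)
  acc_fit <- fit_accuracy_model(cohort$events)
  tlx_ratings <- unique(cohort$events[, c("participant_id", "snr", "tlx_score")])
  names(tlx_ratings)[3] <- "tlx"
  tlx_fit <- fit_tlx_model(tlx_ratings)

  shapes <- shape_table(prep$cell_means)
  wg <- wordgroup_analysis(prep$cell_means, cohort$profiles)
  shapes_out <- merge(shapes, wg$groups, by = "participant_id")
  write_table(shapes_out, cfg$outdir, "shape_params.csv")

  behavior <- stats::aggregate(
    cbind(prop_correct = keywords_correct / n_keywords, tlx_mean = tlx_score) ~
      participant_id, data = cohort$events, FUN = mean)
  cors <- correlation_table(cohort$profiles, shapes, behavior,
                            m = cfg$bonferroni_m)
  write_table(cors, cfg$outdir, "correlation_table.csv")
  mods <- moderated_regressions(shapes, cohort$profiles, wg$groups)
  write_table(mods, cfg$outdir, "moderated_regressions.csv")

  summaries <- list(condition = fit_to_list(cond_fit),
                    polynomial = fit_to_list(poly_fit),
                    accuracy = fit_to_list(acc_fit),
                    tlx = fit_to_list(tlx_fit),
                    wordgroup_interaction = fit_to_list(wg$interaction),
                    wordgroup_covariate_tests = wg$covariate_tests)
  jsonlite::write_json(summaries, file.path(cfg$outdir, "model_summaries.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       na = "null")

  excluded_fraction <- mean(!prep$trial_metrics$included)
  manifest <- list(
    package_version = as.character(utils::packageVersion("pupilci")),
    seed = cfg$seed, n_participants = cfg$n_participants, fs = cfg$fs,
    bonferroni_m = cfg$bonferroni_m,
    design = unclass(cfg$design), effect_config = unclass(cfg$config),
    prep_params = unclass(cfg$prep),
    n_trials = nrow(cohort$events),
    n_samples = nrow(cohort$samples),
    n_included_trials = sum(prep$trial_metrics$included),
    excluded_fraction = excluded_fraction)
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(outdir = cfg$outdir, cohort = cohort, prep = prep,
                 fits = list(condition = cond_fit, polynomial = poly_fit,
                             accuracy = acc_fit, tlx = tlx_fit),
                 shapes = shapes_out, wordgroup = wg, correlations = cors,
                 moderated = mods, excluded_fraction = excluded_fraction))
}

#' Render a human-readable summary from a completed run directory
#'
#' Rebuilds per-SNR accuracy/TLX/PPD summaries (mean and SE across
#' participants), per-group PPD-by-SNR tables and the correlation table from
#' the saved CSVs alone (no in-memory state), and writes them to
#' `report.md` in the run directory.
#'
#' @param run_dir a directory written by [run_pipeline()].
#' @return the report path, invisibly; the parsed tables as an attribute-free
#'   list in `$tables`.
#' @export
render_report <- function(run_dir) {
  need <- c("events.csv", "cell_means.csv", "shape_params.csv",
            "correlation_table.csv")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing)) {
    stop("missing artifacts: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  events <- utils::read.csv(file.path(run_dir, "events.csv"))
  cells <- utils::read.csv(file.path(run_dir, "cell_means.csv"))
  shapes <- utils::read.csv(file.path(run_dir, "shape_params.csv"))
  cors <- utils::read.csv(file.path(run_dir, "correlation_table.csv"))

  se <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  summarize_by <- function(df, value, by) {
    agg_m <- stats::aggregate(df[[value]], df[by], mean)
    agg_s <- stats::aggregate(df[[value]], df[by], se)
    names(agg_m)[ncol(agg_m)] <- "mean"
    agg_m$se <- agg_s$x
    agg_m
  }

  events$prop_correct <- events$keywords_correct / events$n_keywords
  per_part_acc <- stats::aggregate(prop_correct ~ participant_id + snr,
                                   events, mean)
  per_part_tlx <- stats::aggregate(tlx_score ~ participant_id + snr,
                                   events, mean)
  acc_snr <- summarize_by(per_part_acc, "prop_correct", "snr")
  tlx_snr <- summarize_by(per_part_tlx, "tlx_score", "snr")
  ppd_snr <- summarize_by(cells[is.finite(cells$ppd), ], "ppd", "snr")
  group_ppd <- if ("wordgroup" %in% names(shapes)) {
    merged <- merge(cells, shapes[, c("participant_id", "wordgroup")],
                    by = "participant_id")
    summarize_by(merged[is.finite(merged$ppd), ], "ppd", c("snr", "wordgroup"))
  } else NULL

  fmt <- function(df) paste(utils::capture.output(print(df, row.names = FALSE,
                                                        digits = 3)),
                            collapse = "\n")
  lines <- c(
    "# Run summary", "",
    "## Keyword accuracy by SNR (mean, SE across participants)", "",
    fmt(acc_snr), "",
    "## NASA-TLX by SNR", "", fmt(tlx_snr), "",
    "## Peak pupil dilation (%) by SNR", "", fmt(ppd_snr), "",
    if (!is.null(group_ppd)) c("## PPD by SNR and word-recognition group", "",
                               fmt(group_ppd), ""),
    "## Correlation battery", "", fmt(cors), "")
  path <- file.path(run_dir, "report.md")
  writeLines(lines, path)
  invisible(structure(path, tables = list(accuracy = acc_snr, tlx = tlx_snr,
                                          ppd = ppd_snr, group_ppd = group_ppd,
                                          correlations = cors)))
}
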