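#' Effect-size table over metric columns
#'
#' One [hedges_g()] per metric, computed across trials with sample 1 the
#' control group and sample 2 the dyslexia group (negative g therefore means
#' the dyslexia group is larger/longer).
#'
#' @param metrics a metrics table from [cohort_metrics()] (must contain a
#'   `group` column with levels `control` and `dyslexia`).
#' @param metric_cols metric column names; default: all numeric columns.
#' @return data.frame: `metric`, `g`, `ci_lo`, `ci_hi`, `n_control`,
#'   `n_dyslexia`.
#' @export
effect_size_table <- function(metrics, metric_cols = NULL) {
  if (is.null(metric_cols))
    metric_cols <- names(metrics)[vapply(metrics, is.numeric, logical(1))]
  ctrl <- metrics[metrics$group == "control", , drop = FALSE]
  dys <- metrics[metrics$group == "dyslexia", , drop = FALSE]
  rows <- lapply(metric_cols, function(m) {
    x <- ctrl[[m]]; y <- dys[[m]]
    es <- tryCatch(hedges_g_samples(x, y),
                   error = function(e) NULL)
    if (is.null(es)) return(NULL)
    data.frame(metric = m, g = es$g, ci_lo = es$ci[1], ci_hi = es$ci[2],
               n_control = es$n1, n_dyslexia = es$n2)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline on a simulated or loaded cohort
#'
#' simulate (optional) -> clean -> map -> classify -> metrics -> similarity
#' -> group comparison, with deterministic seeding throughout. Stage counts
#' are collected in a manifest mirroring the cleaning reports.
#'
#' @param cohort either a [cohort_spec()] (trials are simulated) or a list of
#'   `trial_record`s with a `layouts` attribute.
#' @param config a [cleaning_config()].
#' @param scasim a [scasim_config()].
#' @param seed seed for the clustering stage (simulation uses the spec's
#'   `master_seed`).
#' @param drift_mode vertical drift-correction mode.
#' @param run_similarity set `FALSE` to skip the (heaviest) similarity stage.
#' @return a `pipeline_result`: list with `metrics`, `effect_sizes`,
#'   `profile` (z-scored group means), `similarity` (per text-font pair),
#'   `manifest`.
#' @export
run_pipeline <- function(cohort, config = cleaning_config(),
                         scasim = scasim_config(), seed = 1L,
                         drift_mode = "off", run_similarity = TRUE) {
  trials <- if (inherits(cohort, "cohort_spec")) simulate_cohort(cohort)
            else cohort
  layouts <- attr(trials, "layouts")
  if (is.null(layouts)) stop("cohort must carry a 'layouts' attribute")
  metrics <- cohort_metrics(trials, layouts, config, drift_mode)
  key_metrics <- c("median_fixdur", "total_scanpath", "median_sacc_amp",
                   "sd_sacc_amp", "first_run_dwell_time",
                   "ratio_first_run_words_skipped", "ratio_visited_words",
                   "fixations_per_word", "n_regressions",
                   "regression_probability", "median_line_initial_fixdur",
                   "n_directional_deviations")
  es <- effect_size_table(metrics, key_metrics)
  prof <- normalize_profile(metrics, key_metrics)
  sim <- NULL
  if (run_similarity) {
    cleaned <- lapply(trials, function(tr) clean_trial(tr, config)$trial)
    cleaned <- cleaned[!vapply(cleaned, function(t)
      isTRUE(t$excluded), logical(1))]
    sim <- similarity_analysis(cleaned, scasim, seed = seed)
  }
  manifest <- list(n_trials_in = length(trials),
                   n_trials_analyzed = nrow(metrics),
                   n_trials_excluded = attr(metrics, "n_excluded"),
                   seed = seed,
                   cleaning = unclass(config)[c("interest_trim_ms",
                                                "min_fix_ms",
                                                "merge_amp_deg",
                                                "min_sacc_amp_deg")])
  structure(list(metrics = metrics, effect_sizes = es,
                 profile = prof$group_means, similarity = sim,
                 manifest = manifest),
            class = "pipeline_result")
}

#' Export pipeline artifacts
#'
#' Writes the metrics table and effect-size table as TSV and the similarity
#' summary, group profile and manifest as JSON, deterministically.
#'
#' @param result a `pipeline_result`.
#' @param dir output directory (created if needed).
#' @param fmt subset of `c("tsv", "json")`.
#' @return character vector of written paths, invisibly.
#' @export
export_report <- function(result, dir, fmt = c("tsv", "json")) {
  stopifnot(inherits(result, "pipeline_result"))
  bad <- setdiff(fmt, c("tsv", "json"))
  if (length(bad)) stop("unknown format: ", paste(bad, collapse = ", "))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  if ("tsv" %in% fmt) {
    p1 <- file.path(dir, "trial_metrics.tsv")
    write.table(result$metrics, p1, sep = "\t", quote = FALSE,
                row.names = FALSE)
    p2 <- file.path(dir, "effect_sizes.tsv")
    write.table(result$effect_sizes, p2, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, p1, p2)
  }
  if ("json" %in% fmt) {
    p3 <- file.path(dir, "report.json")
    jsonlite::write_json(
      list(schema_version = "1.0",
           manifest = result$manifest,
           profile = as.data.frame(result$profile),
           similarity = result$similarity),
      p3, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
    paths <- c(paths, p3)
  }
  invisible(paths)
}
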