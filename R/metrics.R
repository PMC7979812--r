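#' First-pass segmentation of an assigned trial
#'
#' Walks the assigned fixations in time order maintaining a frontier (the
#' largest word index reached). A word's first run is its maximal block of
#' consecutive assigned fixations on first arrival; fixations on words at or
#' behind the frontier outside that block are revisits. A word is skipped
#' during first pass when the frontier moves beyond it before it has received
#' any fixation; later fixations on it remain revisits and never open a first
#' run. Unassigned fixations are ignored here.
#'
#' @param assignment from [assign_fixations()].
#' @param trial the matching `trial_record` (for durations).
#' @param layout the `text_layout`.
#' @return a `first_pass` object: per-word data.frame with
#'   `first_run_dur` (ms), `first_run_nfix`, `skipped_first_pass`,
#'   `visited_ever`, `n_fixations_total`, plus attribute `empty` when no
#'   fixation was assigned.
#' @export
segment_first_pass <- function(assignment, trial, layout) {
  nw <- nrow(layout$words)
  wi <- layout$words$word_index
  seg <- data.frame(word_index = wi,
                    first_run_dur = 0, first_run_nfix = 0L,
                    skipped_first_pass = FALSE, visited_ever = FALSE,
                    n_fixations_total = 0L)
  seq_fix <- which(!is.na(assignment$word_index))
  if (!length(seq_fix)) { attr(seg, "empty") <- TRUE; return(seg) }
  words_seq <- assignment$word_index[seq_fix]
  durs <- trial$fixations$duration[seq_fix]
  frontier <- -1L
  in_run_word <- NA_integer_
  for (k in seq_along(words_seq)) {
    wd <- words_seq[k]
    row <- match(wd, wi)
    seg$n_fixations_total[row] <- seg$n_fixations_total[row] + 1L
    seg$visited_ever[row] <- TRUE
    if (wd > frontier) {
      between <- wi > frontier & wi < wd
      seg$skipped_first_pass[between & !seg$visited_ever] <- TRUE
      frontier <- wd
      in_run_word <- wd
      seg$first_run_dur[row] <- durs[k]
      seg$first_run_nfix[row] <- 1L
    } else if (!is.na(in_run_word) && wd == in_run_word &&
                 !seg$skipped_first_pass[row]) {
      seg$first_run_dur[row] <- seg$first_run_dur[row] + durs[k]
      seg$first_run_nfix[row] <- seg$first_run_nfix[row] + 1L
    } else {
      in_run_word <- NA_integer_   # revisit breaks any open run
    }
  }
  attr(seg, "empty") <- FALSE
  seg
}

#' Word-level (local) reading metrics
#'
#' @param seg a segmentation from [segment_first_pass()].
#' @param layout the `text_layout`.
#' @return one-row data.frame: `first_run_dwell_time` (s, trial total),
#'   `ratio_first_run_words_skipped`, `ratio_visited_words`,
#'   `fixations_per_word` (denominator: all words of the text).
#' @export
compute_local_metrics <- function(seg, layout) {
  nw <- nrow(layout$words)
  data.frame(first_run_dwell_time = sum(seg$first_run_dur) / 1000,
             ratio_first_run_words_skipped = sum(seg$skipped_first_pass) / nw,
             ratio_visited_words = sum(seg$visited_ever) / nw,
             fixations_per_word = sum(seg$n_fixations_total) / nw)
}

#' Trial-level (global) eye-movement metrics
#'
#' Central tendencies of fixation durations and saccade amplitudes, the total
#' scan path (sum of saccade amplitudes in degrees), regression counts from
#' the taxonomy labels, and the directional-deviation count. With zero
#' saccades the amplitude statistics are `NA` and the regression probability
#' 0.
#'
#' @param trial a cleaned `trial_record`.
#' @param labels saccade labels from [label_saccades()].
#' @return one-row data.frame.
#' @export
compute_global_metrics <- function(trial, labels) {
  fx <- trial$fixations
  ns <- nrow(labels)
  amp <- labels$amplitude
  n_reg <- sum(labels$category == "regression")
  data.frame(
    mean_fixdur = if (nrow(fx)) mean(fx$duration) else NA_real_,
    median_fixdur = if (nrow(fx)) median(fx$duration) else NA_real_,
    total_scanpath = if (ns) sum(amp) else 0,
    mean_sacc_amp = if (ns) mean(amp) else NA_real_,
    median_sacc_amp = if (ns) median(amp) else NA_real_,
    sd_sacc_amp = if (ns > 1) sd(amp) else NA_real_,
    n_regressions = n_reg,
    regression_probability = if (ns) n_reg / ns else 0,
    n_directional_deviations =
      sum(labels$category == "directional_deviation"))
}

#' Reading speed in words per minute
#'
#' Uses the untrimmed trial duration (the behavioural reading time from text
#' onset to the reader's key press), not the trimmed interest period.
#'
#' @param trial a `trial_record`.
#' @param layout the `text_layout`.
#' @return words per minute.
#' @export
reading_speed_wpm <- function(trial, layout) {
  if (is.null(trial$trial_duration) || trial$trial_duration <= 0)
    stop("trial_duration must be positive")
  nrow(layout$words) / (trial$trial_duration / 60000)
}

#' All metrics for one trial
#'
#' Convenience wrapper running assignment, taxonomy, segmentation and the
#' metric computations for a cleaned trial.
#'
#' @param trial a cleaned `trial_record`.
#' @param layout the `text_layout`.
#' @param areas optional precomputed interest areas.
#' @return one-row data.frame of labels and all trial metrics, including
#'   `median_line_initial_fixdur` and `reading_duration` (s) and `wpm`.
#' @export
trial_metrics <- function(trial, layout, areas = build_interest_areas(layout)) {
  assignment <- assign_fixations(trial, areas)
  labels <- label_saccades(trial, assignment, layout)
  seg <- segment_first_pass(assignment, trial, layout)
  li <- detect_line_initial(trial, assignment, layout)
  cbind(data.frame(participant = trial$participant_id, group = trial$group,
                   font = trial$font, text = trial$text_id),
        compute_global_metrics(trial, labels),
        compute_local_metrics(seg, layout),
        data.frame(
          median_line_initial_fixdur =
            if (nrow(li)) median(li$duration) else NA_real_,
          reading_duration = trial$trial_duration / 1000,
          wpm = reading_speed_wpm(trial, layout)))
}

#' Metrics table for a cohort
#'
#' Cleans every trial and computes [trial_metrics()] against its text's
#' layout. Excluded trials (too short, or empty after cleaning) are dropped
#' and counted in the attribute `n_excluded`.
#'
#' @param trials list of `trial_record`s (e.g. from [simulate_cohort()]).
#' @param layouts named list of layouts keyed `"<text>_<font>"`.
#' @param config a [cleaning_config()].
#' @param drift_mode vertical drift-correction mode (see
#'   [correct_vertical_drift()]).
#' @return data.frame, one row per analyzed trial.
#' @export
cohort_metrics <- function(trials, layouts = attr(trials, "layouts"),
                           config = cleaning_config(),
                           drift_mode = "off") {
  rows <- list(); n_excl <- 0L
  for (tr in trials) {
    lay <- layouts[[paste(tr$text_id, tr$font, sep = "_")]]
    if (is.null(lay)) stop("no layout for ", tr$text_id, "/", tr$font)
    cl <- clean_trial(tr, config)
    if (isTRUE(cl$trial$excluded)) { n_excl <- n_excl + 1L; next }
    areas <- build_interest_areas(lay)
    t2 <- correct_vertical_drift(cl$trial, areas, mode = drift_mode)$trial
    rows[[length(rows) + 1L]] <- trial_metrics(t2, lay, areas)
  }
  out <- do.call(rbind, rows)
  attr(out, "n_excluded") <- n_excl
  out
}

#' Z-score metric profiles and summarize by group
#'
#' Each metric is z-scored across all trials of both groups; the z-scores are
#' then averaged per group (the radar-plot profile). Metrics with zero
#' variance are flagged and excluded.
#'
#' @param metrics a metrics table from [cohort_metrics()].
#' @param metric_cols metric column names; default: all numeric columns.
#' @return list with `z` (z-scored table), `group_means` (metric x group) and
#'   `excluded` (zero-variance metric names).
#' @export
normalize_profile <- function(metrics, metric_cols = NULL) {
  if (is.null(metric_cols))
    metric_cols <- names(metrics)[vapply(metrics, is.numeric, logical(1))]
  if (nrow(metrics) < 2) stop("need >= 2 trials")
  excluded <- character(0)
  z <- metrics
  for (m in metric_cols) {
    v <- metrics[[m]]
    s <- sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) { excluded <- c(excluded, m); next }
    z[[m]] <- (v - mean(v, na.rm = TRUE)) / s
  }
  keep <- setdiff(metric_cols, excluded)
  gm <- do.call(rbind, lapply(split(z, z$group), function(d)
    colMeans(d[, keep, drop = FALSE], na.rm = TRUE)))
  list(z = z, group_means = gm, excluded = excluded)
}
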