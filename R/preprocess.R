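#' Event-cleaning configuration
#'
#' Thresholds for the standard reading-analysis cleaning pass: a +/- 300 ms
#' interest period, 1 degree fixation merging, 50 ms minimum fixation
#' duration, 0.5 degree minimum saccade amplitude, removal of blink-adjacent
#' fixations, and exclusion of fixations beyond display bounds.
#'
#' @param interest_trim_ms ms trimmed from each end of the trial.
#' @param min_fix_ms minimum retained fixation duration.
#' @param merge_amp_deg merge radius for consecutive fixations (degrees).
#' @param min_sacc_amp_deg minimum derived saccade amplitude (degrees).
#' @param drop_blink_adjacent remove fixations flanking a blink.
#' @param blink_adj_ms temporal window defining "immediately" before/after a
#'   blink: a fixation is blink-adjacent when its edge lies within this many
#'   ms of a blink edge (event streams place blinks a few ms from the
#'   flanking fixations; the window makes the rule idempotent).
#' @param enforce_bounds drop fixations outside the display.
#' @return an object of class `cleaning_config`.
#' @export
cleaning_config <- function(interest_trim_ms = 300, min_fix_ms = 50,
                            merge_amp_deg = 1.0, min_sacc_amp_deg = 0.5,
                            drop_blink_adjacent = TRUE, blink_adj_ms = 50,
                            enforce_bounds = TRUE) {
  vals <- c(interest_trim_ms, min_fix_ms, merge_amp_deg, min_sacc_amp_deg,
            blink_adj_ms)
  if (any(vals < 0)) stop("all thresholds must be >= 0")
  structure(list(interest_trim_ms = interest_trim_ms, min_fix_ms = min_fix_ms,
                 merge_amp_deg = merge_amp_deg,
                 min_sacc_amp_deg = min_sacc_amp_deg,
                 drop_blink_adjacent = drop_blink_adjacent,
                 blink_adj_ms = blink_adj_ms,
                 enforce_bounds = enforce_bounds),
            class = "cleaning_config")
}

#' Restrict a trial to its interest period
#'
#' Removes events lying entirely within the first or last `interest_trim_ms`
#' of the trial; fixations straddling a boundary are clipped to it and their
#' duration recomputed. Trials shorter than twice the trim are flagged
#' `excluded`.
#'
#' @param trial a `trial_record`.
#' @param config a [cleaning_config()].
#' @return the trimmed trial; `trial$excluded` is `TRUE` when the trial was
#'   too short or no event survived.
#' @export
apply_interest_period <- function(trial, config = cleaning_config()) {
  lo <- config$interest_trim_ms
  hi <- trial$trial_duration - config$interest_trim_ms
  if (hi <= lo) {
    trial$excluded <- TRUE
    trial$exclusion_reason <- "trial shorter than twice the interest trim"
    return(trial)
  }
  clip <- function(ev) {
    if (!nrow(ev)) return(ev)
    keep <- ev$offset > lo & ev$onset < hi
    ev <- ev[keep, , drop = FALSE]
    if (nrow(ev)) {
      clipped <- ev$onset < lo | ev$offset > hi
      ev$onset <- pmax(ev$onset, lo)
      ev$offset <- pmin(ev$offset, hi)
      if ("duration" %in% names(ev) && any(clipped))
        ev$duration[clipped] <- ev$offset[clipped] - ev$onset[clipped]
    }
    ev
  }
  trial$fixations <- clip(trial$fixations)
  trial$saccades <- clip(trial$saccades)
  trial$blinks <- clip(trial$blinks)
  if (!nrow(trial$fixations)) {
    trial$excluded <- TRUE
    trial$exclusion_reason <- "no fixation inside the interest period"
  }
  trial
}

#' Merge close fixations and filter short, blink-adjacent and out-of-bounds ones
#'
#' Rule order: blink-adjacent removal, pairwise-sequential left-to-right
#' merging of consecutive fixations closer than `merge_amp_deg` (durations
#' summed, position the duration-weighted mean; never across a blink),
#' minimum-duration filter, display-bounds filter. Merging precedes the
#' duration filter so short refixation fragments can survive as merged
#' fixations.
#'
#' @param trial a `trial_record` (interest period already applied).
#' @param config a [cleaning_config()].
#' @param geometry a [display_geometry()].
#' @return `list(trial = cleaned trial, report = cleaning_report)`; the
#'   report counts removals per rule and satisfies
#'   `input = retained + removed`.
#' @export
merge_and_filter_fixations <- function(trial, config = cleaning_config(),
                                       geometry = trial$geometry) {
  fx <- trial$fixations
  bl <- trial$blinks
  n_in <- nrow(fx)
  n_blink_adj <- 0L
  if (config$drop_blink_adjacent && nrow(bl) && nrow(fx)) {
    adj <- rep(FALSE, nrow(fx))
    for (b in seq_len(nrow(bl))) {
      adj <- adj |
        (fx$offset <= bl$onset[b] &
           bl$onset[b] - fx$offset <= config$blink_adj_ms) |
        (fx$onset >= bl$offset[b] &
           fx$onset - bl$offset[b] <= config$blink_adj_ms)
    }
    n_blink_adj <- sum(adj)
    fx <- fx[!adj, , drop = FALSE]
  }
  blink_between <- function(t0, t1) {
    nrow(bl) && any(bl$onset < t1 & bl$offset > t0)
  }
  n_merged <- 0L
  if (nrow(fx) > 1) {
    out <- fx[1, , drop = FALSE]
    for (i in 2:nrow(fx)) {
      cur <- out[nrow(out), ]
      nxt <- fx[i, ]
      d_deg <- px_to_deg(sqrt((nxt$x - cur$x)^2 + (nxt$y - cur$y)^2), geometry)
      if (d_deg < config$merge_amp_deg &&
          !blink_between(cur$offset, nxt$onset)) {
        w <- c(cur$duration, nxt$duration)
        out[nrow(out), "x"] <- sum(w * c(cur$x, nxt$x)) / sum(w)
        out[nrow(out), "y"] <- sum(w * c(cur$y, nxt$y)) / sum(w)
        out[nrow(out), "offset"] <- nxt$offset
        out[nrow(out), "duration"] <- sum(w)
        n_merged <- n_merged + 1L
      } else {
        out <- rbind(out, nxt)
      }
    }
    fx <- out
  }
  short <- fx$duration < config$min_fix_ms
  n_short <- sum(short)
  fx <- fx[!short, , drop = FALSE]
  n_oob <- 0L
  if (config$enforce_bounds && nrow(fx)) {
    oob <- fx$x < 0 | fx$x > geometry$width_px |
      fx$y < 0 | fx$y > geometry$height_px
    n_oob <- sum(oob)
    fx <- fx[!oob, , drop = FALSE]
  }
  rownames(fx) <- NULL
  trial$fixations <- fx
  report <- data.frame(input_fixations = n_in,
                       blink_adjacent_removed = n_blink_adj,
                       merged_away = n_merged,
                       short_removed = n_short,
                       out_of_bounds_removed = n_oob,
                       retained_fixations = nrow(fx))
  list(trial = trial, report = report)
}

#' Re-derive saccades from cleaned fixations
#'
#' One candidate saccade per pair of consecutive retained fixations (start:
#' earlier fixation's position and offset; end: later fixation's position and
#' onset). Displacements below `min_sacc_amp_deg` yield no saccade record.
#' Saccades whose time span contains a blink get `blink_flag = TRUE`.
#'
#' @inheritParams merge_and_filter_fixations
#' @return the trial with a rebuilt `saccades` data.frame (columns include
#'   `from_fix`/`to_fix` row indices into `fixations` and `blink_flag`).
#' @export
derive_saccades <- function(trial, config = cleaning_config(),
                            geometry = trial$geometry) {
  fx <- trial$fixations
  bl <- trial$blinks
  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
                      y1 = numeric(0), amplitude = numeric(0),
                      from_fix = integer(0), to_fix = integer(0),
                      blink_flag = logical(0))
  if (nrow(fx) < 2) { trial$saccades <- empty; return(trial) }
  i <- seq_len(nrow(fx) - 1L)
  amp <- px_to_deg(sqrt((fx$x[i + 1] - fx$x[i])^2 +
                          (fx$y[i + 1] - fx$y[i])^2), geometry)
  keep <- amp >= config$min_sacc_amp_deg
  sc <- data.frame(onset = fx$offset[i], offset = fx$onset[i + 1],
                   x0 = fx$x[i], y0 = fx$y[i],
                   x1 = fx$x[i + 1], y1 = fx$y[i + 1],
                   amplitude = amp, from_fix = i, to_fix = i + 1L)[keep, ,
                                                                   drop = FALSE]
  sc$blink_flag <- vapply(seq_len(nrow(sc)), function(k) {
    nrow(bl) > 0 && any(bl$onset < sc$offset[k] & bl$offset > sc$onset[k])
  }, logical(1))
  rownames(sc) <- NULL
  trial$saccades <- sc
  trial
}

#' Full cleaning pass
#'
#' Applies, in order: interest-period trimming, blink-adjacent removal,
#' merging, minimum-duration filter, bounds filter, saccade re-derivation.
#'
#' @inheritParams merge_and_filter_fixations
#' @return `list(trial, report)`; `trial$excluded` is set for unusable trials.
#' @export
clean_trial <- function(trial, config = cleaning_config(),
                        geometry = trial$geometry) {
  trial <- apply_interest_period(trial, config)
  if (isTRUE(trial$excluded)) {
    return(list(trial = trial,
                report = data.frame(input_fixations = nrow(trial$fixations),
                                    blink_adjacent_removed = 0L,
                                    merged_away = 0L, short_removed = 0L,
                                    out_of_bounds_removed = 0L,
                                    retained_fixations = 0L,
                                    excluded = TRUE)))
  }
  mf <- merge_and_filter_fixations(trial, config, geometry)
  trial <- derive_saccades(mf$trial, config, geometry)
  mf$report$excluded <- FALSE
  list(trial = trial, report = mf$report)
}
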