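# Fixture builders used across the suite. Everything is constructed in code;
# no data files.

default_geom <- display_geometry()

# a text_layout on a fixed character grid: `words_per_line` words per line,
# all of `word_chars` characters
make_grid_layout <- function(n_lines = 2, words_per_line = 10, word_chars = 5,
                             char_px = 11, line_spacing_px = 55,
                             char_height_px = 19, margin_x = 30,
                             margin_y = 60, geometry = default_geom) {
  pitch <- (word_chars + 1) * char_px
  rows <- list()
  wi <- 0L
  for (li in seq_len(n_lines) - 1L) {
    for (k in seq_len(words_per_line) - 1L) {
      x0 <- margin_x + k * pitch
      rows[[length(rows) + 1L]] <- data.frame(
        word_index = wi, line_index = li,
        x0 = x0, y0 = margin_y + li * line_spacing_px,
        x1 = x0 + word_chars * char_px,
        y1 = margin_y + li * line_spacing_px + char_height_px,
        char_count = word_chars)
      wi <- wi + 1L
    }
  }
  structure(list(words = do.call(rbind, rows), line_count = n_lines,
                 line_spacing_px = line_spacing_px, char_px = char_px,
                 display_bounds = c(0, 0, geometry$width_px,
                                    geometry$height_px)),
            class = "text_layout")
}

# a trial_record from raw fixation coordinates/durations; events are laid
# out sequentially with `gap_ms` between fixations unless explicit onsets
# are given
make_trial <- function(x, y, dur, gap_ms = 200, onset = NULL,
                       blinks = data.frame(onset = numeric(0),
                                           offset = numeric(0)),
                       lead_ms = 400, trial_duration = NULL,
                       geometry = default_geom, group = "control",
                       participant = "p01", font = "TNR", text = "t01") {
  n <- length(x)
  if (is.null(onset)) {
    onset <- numeric(n)
    t <- lead_ms
    for (i in seq_len(n)) {
      onset[i] <- t
      t <- t + dur[i] + gap_ms
    }
  }
  offset <- onset + dur
  tr <- structure(list(participant_id = participant, group = group,
                       font = font, text_id = text,
                       fixations = data.frame(onset = onset, offset = offset,
                                              x = x, y = y, duration = dur),
                       saccades = data.frame(onset = numeric(0),
                                             offset = numeric(0),
                                             x0 = numeric(0), y0 = numeric(0),
                                             x1 = numeric(0), y1 = numeric(0),
                                             amplitude = numeric(0)),
                       blinks = blinks, geometry = geometry,
                       trial_duration = if (is.null(trial_duration))
                         max(offset, blinks$offset, 0) + lead_ms
                       else trial_duration,
                       truth = NULL),
                  class = "trial_record")
  tr
}

# random scanpath for similarity tests
random_scanpath <- function(n, xr = c(50, 950), yr = c(60, 700),
                            dr = c(60, 400)) {
  data.frame(x = runif(n, xr[1], xr[2]), y = runif(n, yr[1], yr[2]),
             duration = runif(n, dr[1], dr[2]))
}

# a two-line trial with a target saccade at a controlled angle, embedded in
# one of four classification contexts
angle_context <- function(theta, context, amp_px = 61) {
  lay <- make_grid_layout(n_lines = 2, words_per_line = 10)
  w <- lay$words
  launch_row <- if (context %in% c("sweep", "undersweep")) w[10, ] else w[5, ]
  x0 <- (launch_row$x0 + launch_row$x1) / 2
  y0 <- (launch_row$y0 + launch_row$y1) / 2
  x1 <- x0 + amp_px * cos(theta * pi / 180)
  y1 <- y0 - amp_px * sin(theta * pi / 180)
  x2 <- x1 + if (context == "undersweep") -150 else 80
  tr <- make_trial(x = c(x0, x1, x2), y = c(y0, y1, y1),
                   dur = c(180, 180, 180), gap_ms = 200,
                   trial_duration = 5000)
  if (context == "blink") {
    mid <- (tr$fixations$offset[1] + tr$fixations$onset[2]) / 2
    tr$blinks <- data.frame(onset = mid - 30, offset = mid + 30)
  }
  tr <- derive_saccades(tr)
  list(trial = tr, layout = lay,
       assignment = assign_fixations(tr, build_interest_areas(lay)))
}
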