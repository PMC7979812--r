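#' Simulate one reading trial
#'
#' Generates an ordered fixation/saccade/blink event stream for one reader
#' traversing a text layout. The walk advances word by word with
#' length-dependent skipping, refixations (landing at the opposite end of the
#' word), same-line regressions followed by a return to the launch word, a
#' return-sweep at every line change (with probability `undersweep_prob`
#' landing mid-line and corrected by a leftward saccade), Poisson-distributed
#' directional-deviation excursion/return pairs whose excursion lands in the
#' inter-line gap (outside every word box), and Poisson-distributed blinks.
#' Fixation durations are lognormal around the profile's median, with the
#' first fixation of each line inflated by `line_initial_inflation`.
#' Inter-fixation gaps are 20 ms plus 2 ms per degree of saccade amplitude.
#'
#' @param layout a `text_layout` from [generate_layout()].
#' @param profile a [reader_profile()].
#' @param seed integer seed; trials are bit-reproducible given the seed.
#' @param participant_id,group,font,text_id trial labels.
#' @param geometry a [display_geometry()].
#' @return a `trial_record`: list with `fixations` (onset, offset, x, y,
#'   duration), `saccades`, `blinks`, labels, `trial_duration`, `geometry`,
#'   and a `truth` element holding the generator's ground truth (inserted
#'   deviations, line-transition types, regression events, per-fixation
#'   target words and roles).
#' @export
simulate_trial <- function(layout, profile, seed,
                           participant_id = "p01", group = "control",
                           font = "TNR", text_id = "t01",
                           geometry = display_geometry()) {
  stopifnot(inherits(layout, "text_layout"), inherits(profile, "reader_profile"))
  set.seed(as.integer(seed))
  noise <- profile$landing_noise_sd
  words <- layout$words
  lis <- sort(unique(words$line_index))

  px <- numeric(0); py <- numeric(0); pword <- integer(0)
  prole <- character(0); pline <- integer(0)
  add <- function(x, y, word, role, line) {
    px[length(px) + 1] <<- x; py[length(py) + 1] <<- y
    pword[length(pword) + 1] <<- word
    prole[length(prole) + 1] <<- role
    pline[length(pline) + 1] <<- line
  }
  land <- function(row, frac) {
    c(row$x0 + frac * (row$x1 - row$x0) + rnorm(1, 0, noise),
      (row$y0 + row$y1) / 2 + rnorm(1, 0, noise))
  }
  skip_p <- function(len) {
    min(0.95, max(0, profile$skip_prob *
                    (1 + profile$skip_len_slope * (5 - len))))
  }

  transitions <- list()
  n_regression_events <- 0L
  for (li in lis) {
    lw <- .line_words(layout, li)
    nl <- nrow(lw)
    visited <- logical(nl)
    if (li == lis[1]) {
      e <- 1L
      xy <- land(lw[e, ], 0.3)
      add(xy[1], xy[2], lw$word_index[e], "line_initial", li)
    } else {
      undersweep <- nl >= 6 && runif(1) < profile$undersweep_prob
      if (undersweep) {
        u <- if (nl <= 4) 4L else sample(4:min(nl, 8), 1L)
        xy <- land(lw[u, ], 0.4)
        add(xy[1], xy[2], lw$word_index[u], "undersweep_landing", li)
        visited[u] <- TRUE
      }
      # sweeps land on word 1, or word 2 when word 1 is skipped
      e <- if (nl >= 2 && runif(1) < skip_p(lw$char_count[1])) 2L else 1L
      xy <- land(lw[e, ], 0.3)
      add(xy[1], xy[2], lw$word_index[e], "line_initial", li)
      transitions[[length(transitions) + 1L]] <-
        data.frame(to_line = li,
                   type = if (undersweep) "undersweep" else "sweep",
                   landing_pos = e)
    }
    visited[e] <- TRUE
    i <- e
    repeat {
      row <- lw[i, ]
      if (row$char_count >= 6 && runif(1) < profile$refixation_prob) {
        xy <- land(row, 0.8)
        add(xy[1], xy[2], row$word_index, "refix", li)
      }
      if (runif(1) < profile$regression_prob && i > 2) {
        elig <- which(visited[seq_len(i - 2L)])
        if (length(elig)) {
          tgt <- if (length(elig) == 1L) elig else sample(elig, 1L)
          xy <- land(lw[tgt, ], 0.5)
          add(xy[1], xy[2], lw$word_index[tgt], "regression_target", li)
          xy <- land(row, 0.6)
          add(xy[1], xy[2], row$word_index, "regression_return", li)
          n_regression_events <- n_regression_events + 1L
        }
      }
      j <- i + 1L
      while (j <= nl && runif(1) < skip_p(lw$char_count[j])) j <- j + 1L
      if (j > nl) break
      xy <- land(lw[j, ], 0.3)
      add(xy[1], xy[2], lw$word_index[j], "reading", li)
      visited[j] <- TRUE
      i <- j
    }
    # record the launch rank (from the line end) of the upcoming sweep
    if (li != lis[length(lis)])
      attr(transitions, "pending_launch") <-
        c(attr(transitions, "pending_launch"), nl - i + 1L)
  }
  launches <- attr(transitions, "pending_launch")
  transitions <- if (length(transitions)) do.call(rbind, transitions) else
    data.frame(to_line = integer(0), type = character(0),
               landing_pos = integer(0))
  if (nrow(transitions)) transitions$launch_pos_from_end <- launches

  # --- directional-deviation excursion/return pairs -----------------------
  drop_px <- 35                       # > 1 deg merge radius, lands between lines
  dx_min <- 63                        # keeps the return saccade below 35 deg
  n <- length(px)
  line_tab <- table(words$line_index)
  pos_in_line <- stats::ave(rep(1, nrow(words)), words$line_index,
                            FUN = seq_along)[match(pword, words$word_index)]
  eligible <- which(
    prole[seq_len(max(0, n - 1))] %in%
      c("reading", "refix", "regression_return", "line_initial") &
      !is.na(pword[seq_len(max(0, n - 1))]) &
      pline[seq_len(max(0, n - 1))] == pline[seq_len(max(0, n - 1)) + 1L] &
      (px[seq_len(max(0, n - 1)) + 1L] - px[seq_len(max(0, n - 1))]) >= dx_min &
      pos_in_line[seq_len(max(0, n - 1))] <=
        as.integer(line_tab[as.character(pline[seq_len(max(0, n - 1))])]) - 4L)
  n_dev <- min(rpois(1, profile$deviation_rate), length(eligible))
  dev_at <- if (n_dev > 0) sort(sample(eligible, n_dev), decreasing = TRUE)
            else integer(0)
  sgn <- if (profile$deviation_angle_mode == "down") 1 else -1
  for (k in dev_at) {
    # anchor the drop at the word box centre (not the jittered landing) so
    # the excursion always ends in the inter-line gap, outside every area
    wrow <- words[match(pword[k], words$word_index), ]
    ex <- c(px[k] - 20, (wrow$y0 + wrow$y1) / 2 + sgn * drop_px)
    px <- append(px, ex[1], after = k); py <- append(py, ex[2], after = k)
    pword <- append(pword, NA_integer_, after = k)
    prole <- append(prole, "deviation_excursion", after = k)
    pline <- append(pline, pline[k], after = k)
  }
  n <- length(px)

  # --- blinks -------------------------------------------------------------
  near_excursion <- which(prole == "deviation_excursion")
  near_excursion <- unique(c(near_excursion - 1L, near_excursion,
                             near_excursion + 1L))
  gap_ok <- vapply(seq_len(max(0, n - 1L)), function(g) {
    prole[g] %in% c("reading", "refix") &&
      prole[g + 1L] %in% c("reading", "refix") &&
      pline[g] == pline[g + 1L] &&
      !(g %in% near_excursion) && !((g + 1L) %in% near_excursion)
  }, logical(1))
  blink_gaps <- which(gap_ok)
  n_blink <- min(rpois(1, profile$blink_rate), length(blink_gaps))
  blink_at <- if (n_blink > 0) sort(sample(blink_gaps, n_blink)) else integer(0)

  # --- timing assembly ----------------------------------------------------
  dur <- numeric(n)
  for (i in seq_len(n)) {
    dur[i] <- if (prole[i] == "deviation_excursion")
      rlnorm(1, log(100), 0.2)
    else
      rlnorm(1, log(profile$fixdur_median), profile$fixdur_sigma) +
        if (prole[i] == "line_initial") profile$line_initial_inflation else 0
  }
  onset <- numeric(n); offset <- numeric(n)
  blink_on <- numeric(0); blink_off <- numeric(0)
  t <- 400
  for (i in seq_len(n)) {
    onset[i] <- t; offset[i] <- t + dur[i]; t <- offset[i]
    if (i < n) {
      if (i %in% blink_at) {
        bd <- rlnorm(1, log(120), 0.25)
        blink_on <- c(blink_on, t + 30); blink_off <- c(blink_off, t + 30 + bd)
        t <- t + 60 + bd
      } else {
        amp <- px_to_deg(sqrt((px[i + 1] - px[i])^2 + (py[i + 1] - py[i])^2),
                         geometry)
        t <- t + 20 + 2 * amp
      }
    }
  }
  fixations <- data.frame(onset = onset, offset = offset, x = px, y = py,
                          duration = offset - onset)
  saccades <- if (n > 1) data.frame(
    onset = offset[-n], offset = onset[-1],
    x0 = px[-n], y0 = py[-n], x1 = px[-1], y1 = py[-1],
    amplitude = px_to_deg(sqrt(diff(px)^2 + diff(py)^2), geometry))
  else data.frame(onset = numeric(0), offset = numeric(0), x0 = numeric(0),
                  y0 = numeric(0), x1 = numeric(0), y1 = numeric(0),
                  amplitude = numeric(0))
  blinks <- data.frame(onset = blink_on, offset = blink_off)

  structure(list(participant_id = participant_id, group = group, font = font,
                 text_id = text_id,
                 fixations = fixations, saccades = saccades, blinks = blinks,
                 geometry = geometry, trial_duration = t + 400,
                 truth = list(n_deviations_inserted = n_dev,
                              transitions = transitions,
                              n_regression_events = n_regression_events,
                              target_word = pword, role = prole,
                              line = pline)),
            class = "trial_record")
}

#' Simulate a two-group cohort
#'
#' Runs [simulate_trial()] for every participant x text (x font when
#' `font_design = "crossed"`) combination of a [cohort_spec()]. Per-text
#' layouts and per-trial seeds are derived deterministically from
#' `master_seed`, so identical specs reproduce identical cohorts.
#'
#' @param spec a [cohort_spec()].
#' @param geometry a [display_geometry()].
#' @return a list of `trial_record`s with attribute `layouts`, a named list
#'   of `text_layout`s keyed by `"<text>_<font>"`.
#' @export
simulate_cohort <- function(spec, geometry = display_geometry()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_texts == 0) {
    out <- list(); attr(out, "layouts") <- list(); return(out)
  }
  set.seed(spec$master_seed)
  n_words <- sample(spec$n_words_range[1]:spec$n_words_range[2],
                    spec$n_texts, replace = TRUE)
  texts <- sprintf("t%02d", seq_len(spec$n_texts))
  participants <- c(sprintf("c%02d", seq_len(spec$n_control)),
                    sprintf("d%02d", seq_len(spec$n_dyslexia)))
  groups <- rep(c("control", "dyslexia"),
                c(spec$n_control, spec$n_dyslexia))

  font_of_text <- function(t_idx) spec$fonts[1 + (t_idx - 1) %% length(spec$fonts)]
  char_px_of_font <- function(f)
    if (f == spec$fonts[1]) 11 else 11.8   # second font slightly wider
  layouts <- list()
  trials <- list()
  for (t_idx in seq_len(spec$n_texts)) {
    fset <- if (spec$font_design == "crossed") spec$fonts else
      font_of_text(t_idx)
    for (f in fset) {
      f_idx <- match(f, spec$fonts)
      lay <- generate_layout(n_words[t_idx], chars_per_line = 84,
                             char_px = char_px_of_font(f),
                             margin_x = 16,
                             seed = .derive_seed(spec$master_seed, 0L,
                                                 t_idx, f_idx),
                             geometry = geometry)
      key <- paste(texts[t_idx], f, sep = "_")
      layouts[[key]] <- lay
      for (p_idx in seq_along(participants)) {
        prof <- spec$profiles[[groups[p_idx]]]
        tr <- simulate_trial(lay, prof,
                             seed = .derive_seed(spec$master_seed, p_idx,
                                                 t_idx, f_idx),
                             participant_id = participants[p_idx],
                             group = groups[p_idx], font = f,
                             text_id = texts[t_idx], geometry = geometry)
        trials[[length(trials) + 1L]] <- tr
      }
    }
  }
  attr(trials, "layouts") <- layouts
  trials
}
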