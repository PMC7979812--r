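#' Reader profile for the scanpath simulator
#'
#' Bundles the behavioural parameters that shape one simulated reader's
#' scanpaths. The two built-in profiles, [control_profile()] and
#' [dyslexia_profile()], encode the group-level reading signatures of typical
#' adult readers and adult readers with dyslexia: fixation-duration medians of
#' 202 vs 224 ms, line-initial inflations of 14 vs 32 ms, directional
#' deviation rates of 0.441 vs 1.003 per trial with opposite (upward vs
#' downward) modal directions, more word skipping and larger saccades in the
#' control profile, and more refixations in the dyslexia profile.
#'
#' @param fixdur_median median fixation duration in ms (>= 50).
#' @param fixdur_sigma log-scale spread of the lognormal duration model.
#' @param line_initial_inflation ms added to the first fixation of each line.
#' @param refixation_prob probability of refixating a word (only words of
#'   >= 6 characters are refixated, so that refixations stay outside the 1
#'   degree merging radius).
#' @param skip_prob baseline probability of skipping a word during first-pass
#'   reading.
#' @param skip_len_slope multiplicative length dependence of skipping:
#'   `p = skip_prob * (1 + skip_len_slope * (5 - char_count))`, clamped to
#'   `[0, 0.95]`. Zero `skip_prob` therefore always forces zero skipping.
#' @param regression_prob per-fixation hazard of launching a regression to an
#'   earlier visited word of the same line (followed by a return saccade).
#' @param deviation_rate expected number of directional-deviation
#'   excursion/return pairs inserted per trial (Poisson).
#' @param deviation_angle_mode `"down"` or `"up"`: side of the reading axis
#'   the excursion jumps to.
#' @param undersweep_prob probability that a line change is an undersweep
#'   (landing mid-line, followed by a leftward corrective saccade).
#' @param blink_rate expected blinks per trial (Poisson).
#' @param landing_noise_sd Gaussian jitter (px) on fixation landing sites.
#' @return an object of class `reader_profile`.
#' @export
reader_profile <- function(fixdur_median = 210, fixdur_sigma = 0.3,
                           line_initial_inflation = 20,
                           refixation_prob = 0.2,
                           skip_prob = 0.25, skip_len_slope = 0.1,
                           regression_prob = 0.12,
                           deviation_rate = 0.5,
                           deviation_angle_mode = c("down", "up"),
                           undersweep_prob = 0.2,
                           blink_rate = 0.5,
                           landing_noise_sd = 3) {
  deviation_angle_mode <- match.arg(deviation_angle_mode)
  probs <- c(refixation_prob, skip_prob, regression_prob, undersweep_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (fixdur_median < 50) stop("fixdur_median must be >= 50 ms")
  if (deviation_rate < 0 || blink_rate < 0) stop("rates must be >= 0")
  structure(list(fixdur_median = fixdur_median, fixdur_sigma = fixdur_sigma,
                 line_initial_inflation = line_initial_inflation,
                 refixation_prob = refixation_prob,
                 skip_prob = skip_prob, skip_len_slope = skip_len_slope,
                 regression_prob = regression_prob,
                 deviation_rate = deviation_rate,
                 deviation_angle_mode = deviation_angle_mode,
                 undersweep_prob = undersweep_prob,
                 blink_rate = blink_rate,
                 landing_noise_sd = landing_noise_sd),
            class = "reader_profile")
}

#' @rdname reader_profile
#' @export
control_profile <- function() {
  reader_profile(fixdur_median = 202, fixdur_sigma = 0.3,
                 line_initial_inflation = 14,
                 refixation_prob = 0.15,
                 skip_prob = 0.35, skip_len_slope = 0.1,
                 regression_prob = 0.12,
                 deviation_rate = 0.441, deviation_angle_mode = "up",
                 undersweep_prob = 0.15, blink_rate = 0.5,
                 landing_noise_sd = 3)
}

#' @rdname reader_profile
#' @export
dyslexia_profile <- function() {
  reader_profile(fixdur_median = 224, fixdur_sigma = 0.3,
                 line_initial_inflation = 32,
                 refixation_prob = 0.35,
                 skip_prob = 0.15, skip_len_slope = 0.1,
                 regression_prob = 0.12,
                 deviation_rate = 1.003, deviation_angle_mode = "down",
                 undersweep_prob = 0.3, blink_rate = 0.5,
                 landing_noise_sd = 3)
}

#' Cohort specification for the simulator
#'
#' @param n_control,n_dyslexia participants per group (>= 1, unless
#'   `n_texts` is 0).
#' @param n_texts number of texts; each gets its own generated layout.
#' @param fonts font labels. With `font_design = "alternate"` each text is
#'   shown in exactly one font (alternating, as when half the texts of a
#'   battery are set in each font, giving `(n_control + n_dyslexia) * n_texts`
#'   trials); with `"crossed"` every text is read in every font.
#' @param profiles named list with elements `control` and `dyslexia`, each a
#'   [reader_profile()].
#' @param master_seed integer; all per-trial and per-layout seeds derive from
#'   it deterministically.
#' @param n_words_range range of words per text (sampled per text).
#' @param font_design `"alternate"` or `"crossed"` (see `fonts`).
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control, n_dyslexia, n_texts,
                        fonts = c("TNR", "OD"),
                        profiles = list(control = control_profile(),
                                        dyslexia = dyslexia_profile()),
                        master_seed = 1L,
                        n_words_range = c(140, 160),
                        font_design = c("alternate", "crossed")) {
  font_design <- match.arg(font_design)
  if (n_texts > 0 && (n_control < 1 || n_dyslexia < 1))
    stop("need at least one participant per group")
  stopifnot(all(c("control", "dyslexia") %in% names(profiles)))
  structure(list(n_control = n_control, n_dyslexia = n_dyslexia,
                 n_texts = n_texts, fonts = fonts, profiles = profiles,
                 master_seed = as.integer(master_seed),
                 n_words_range = n_words_range, font_design = font_design),
            class = "cohort_spec")
}

# deterministic sub-seed derivation; kept well below 2^31
.derive_seed <- function(master, p_idx, t_idx, f_idx) {
  as.integer((abs(as.numeric(master)) %% 1e6) * 1009 +
               p_idx * 104729 + t_idx * 1299 + f_idx * 131) %% 2147483629L
}
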