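# build an assignment + trial pair straight from a word sequence
seq_fixture <- function(words, durs = rep(200, length(words)), nw = 4) {
  lay <- make_grid_layout(n_lines = 1, words_per_line = nw)
  tr <- make_trial(x = seq(100, by = 50, length.out = length(words)),
                   y = rep(100, length(words)), dur = durs,
                   trial_duration = 60000)
  asg <- data.frame(fix = seq_along(words), word_index = words,
                    line_index = 0L, in_ia = !is.na(words))
  list(lay = lay, tr = tr, asg = asg)
}

test_that("first-pass segmentation follows the frontier rule", {
  f <- seq_fixture(c(0L, 1L, 2L, 3L))
  seg <- segment_first_pass(f$asg, f$tr, f$lay)
  expect_equal(sum(seg$skipped_first_pass), 0)
  expect_equal(seg$first_run_nfix, rep(1L, 4))

  # word 1 first fixated after the frontier reached 2: skipped, fixation a revisit
  f2 <- seq_fixture(c(0L, 2L, 1L, 3L))
  seg2 <- segment_first_pass(f2$asg, f2$tr, f2$lay)
  expect_true(seg2$skipped_first_pass[seg2$word_index == 1])
  expect_equal(seg2$first_run_nfix[seg2$word_index == 1], 0L)
  expect_true(seg2$visited_ever[seg2$word_index == 1])
  expect_equal(seg2$n_fixations_total[seg2$word_index == 1], 1L)

  # consecutive refixation extends the first run
  f3 <- seq_fixture(c(0L, 0L, 1L), durs = c(100, 150, 200))
  seg3 <- segment_first_pass(f3$asg, f3$tr, f3$lay)
  expect_equal(seg3$first_run_nfix[1], 2L)
  expect_equal(seg3$first_run_dur[1], 250)

  # a regression breaks the run: the return is a revisit
  f4 <- seq_fixture(c(0L, 1L, 0L, 1L, 2L))
  seg4 <- segment_first_pass(f4$asg, f4$tr, f4$lay)
  expect_equal(seg4$first_run_nfix[seg4$word_index == 1], 1L)
  expect_equal(seg4$n_fixations_total[seg4$word_index == 1], 2L)

  # empty assignment flags the segmentation
  f5 <- seq_fixture(c(NA_integer_, NA_integer_))
  expect_true(attr(segment_first_pass(f5$asg, f5$tr, f5$lay), "empty"))
})

test_that("local metrics reduce to the forced arithmetic on uniform trials", {
  lay <- make_grid_layout(n_lines = 10, words_per_line = 15)  # 150 words
  words <- lay$words$word_index
  tr <- make_trial(x = rep(100, 150), y = rep(100, 150), dur = rep(200, 150),
                   trial_duration = 120000)
  asg <- data.frame(fix = seq_len(150), word_index = words, line_index = 0L,
                    in_ia = TRUE)
  seg <- segment_first_pass(asg, tr, lay)
  lm <- compute_local_metrics(seg, lay)
  expect_equal(lm$first_run_dwell_time, 30)       # 150 x 200 ms = 30 s
  expect_equal(lm$ratio_first_run_words_skipped, 0)
  expect_equal(lm$ratio_visited_words, 1)
  expect_equal(lm$fixations_per_word, 1)

  # all words but the first skipped
  asg2 <- data.frame(fix = 1:2, word_index = c(0L, 149L), line_index = 0L,
                     in_ia = TRUE)
  tr2 <- make_trial(x = c(100, 200), y = c(100, 100), dur = c(200, 200),
                    trial_duration = 60000)
  seg2 <- segment_first_pass(asg2, tr2, lay)
  lm2 <- compute_local_metrics(seg2, lay)
  expect_equal(lm2$ratio_first_run_words_skipped, 148 / 150)
  expect_equal(lm2$ratio_visited_words, 2 / 150)
})

test_that("global metrics aggregate amplitudes and regressions correctly", {
  lab <- data.frame(angle = c(0, 0, 0), amplitude = c(2, 2, 6),
                    category = c("forward", "forward", "forward"))
  tr <- make_trial(x = 1:4 * 100, y = rep(100, 4), dur = rep(200, 4),
                   trial_duration = 5000)
  gm <- compute_global_metrics(tr, lab)
  expect_equal(gm$total_scanpath, 10)
  expect_equal(gm$median_sacc_amp, 2)
  expect_equal(gm$mean_sacc_amp, 10 / 3)
  expect_equal(gm$n_regressions, 0)
  expect_equal(gm$regression_probability, 0)

  lab$category[2] <- "regression"
  gm2 <- compute_global_metrics(tr, lab)
  expect_equal(gm2$n_regressions, 1)
  expect_equal(gm2$regression_probability, 1 / 3)

  # no saccades: amplitude statistics undefined, probability zero
  gm0 <- compute_global_metrics(tr, lab[0, ])
  expect_true(is.na(gm0$median_sacc_amp))
  expect_equal(gm0$regression_probability, 0)
})

test_that("reading speed is words over minutes of full trial time", {
  lay <- make_grid_layout(n_lines = 10, words_per_line = 15)
  tr <- make_trial(x = 100, y = 100, dur = 200, trial_duration = 60000)
  expect_equal(reading_speed_wpm(tr, lay), 150)
  tr2 <- tr; tr2$trial_duration <- 30000
  expect_equal(reading_speed_wpm(tr2, lay), 300)
  tr3 <- tr; tr3$trial_duration <- 0
  expect_error(reading_speed_wpm(tr3, lay), "positive")
  # control-like scale anchor: ~150 words in ~36 s is ~248 wpm
  tr4 <- tr; tr4$trial_duration <- 36250
  expect_equal(reading_speed_wpm(tr4, lay), 248.28, tolerance = 1e-4)
})

test_that("detected regressions match the generator's ground truth", {
  lay <- generate_layout(150, seed = 3)
  areas <- build_interest_areas(lay)
  prof <- dyslexia_profile(); prof$blink_rate <- 0
  for (s in 1:20) {
    tr <- simulate_trial(lay, prof, seed = 7000 + s)
    cl <- clean_trial(tr)$trial
    lab <- label_saccades(cl, assign_fixations(cl, areas), lay)
    # every generated regression plus one corrective regression per undersweep
    expect_equal(sum(lab$category == "regression"),
                 tr$truth$n_regression_events +
                   sum(tr$truth$transitions$type == "undersweep"))
  }
})

test_that("all trial metrics agree with an independent brute-force recomputation", {
  lay <- generate_layout(150, seed = 3)
  areas <- build_interest_areas(lay)
  n_checked <- 0
  for (s in 1:50) {
    prof <- if (s %% 2) dyslexia_profile() else control_profile()
    tr <- clean_trial(simulate_trial(lay, prof, seed = 1500 + s))$trial
    m <- trial_metrics(tr, lay, areas)
    o <- oracle_metrics(tr, lay)
    expect_equal(m$mean_fixdur, o$mean_fixdur)
    expect_equal(m$median_fixdur, o$median_fixdur)
    expect_equal(m$total_scanpath, o$total_scanpath)
    expect_equal(m$median_sacc_amp, o$median_sacc_amp)
    expect_equal(m$first_run_dwell_time, o$first_run_dwell_time)
    expect_equal(m$ratio_first_run_words_skipped,
                 o$ratio_first_run_words_skipped)
    expect_equal(m$ratio_visited_words, o$ratio_visited_words)
    expect_equal(m$fixations_per_word, o$fixations_per_word)
    expect_equal(m$wpm, o$wpm)
    # regression count against the independent classifier
    asg <- assign_fixations(tr, areas)
    expect_equal(m$n_regressions,
                 sum(oracle_classify(tr, asg, lay) == "regression"))
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 50)
})

test_that("inserting an extra regression raises the count by exactly one", {
  f <- seq_fixture(c(0L, 1L, 2L, 3L), nw = 4)
  lay <- f$lay
  w <- lay$words
  ctr <- function(i) c(mean(c(w$x0[i], w$x1[i])), mean(c(w$y0[i], w$y1[i])))
  path <- rbind(ctr(1), ctr(2), ctr(3), ctr(4))
  base <- derive_saccades(make_trial(x = path[, 1], y = path[, 2],
                                     dur = rep(200, 4),
                                     trial_duration = 6000))
  asgb <- assign_fixations(base, build_interest_areas(lay))
  labb <- label_saccades(base, asgb, lay)
  n0 <- sum(labb$category == "regression")
  # revisit word 1 after reaching word 3, then return
  path2 <- rbind(ctr(1), ctr(2), ctr(3), ctr(1), ctr(4))
  aug <- derive_saccades(make_trial(x = path2[, 1], y = path2[, 2],
                                    dur = rep(200, 5),
                                    trial_duration = 6000))
  asga <- assign_fixations(aug, build_interest_areas(lay))
  laba <- label_saccades(aug, asga, lay)
  expect_equal(sum(laba$category == "regression"), n0 + 1)
})

test_that("z-scored profiles centre at zero and expose known group shifts", {
  m <- data.frame(group = rep(c("control", "dyslexia"), each = 50),
                  metric_a = rep(c(0, 1), each = 50),
                  metric_b = rnorm(100, 5, 1),
                  constant = 1)
  out <- normalize_profile(m, c("metric_a", "metric_b", "constant"))
  expect_equal(out$excluded, "constant")
  gap <- out$group_means["control", "metric_a"] -
    out$group_means["dyslexia", "metric_a"]
  expect_equal(unname(gap), -1 / sd(m$metric_a))
  # identical distributions: group means near zero
  expect_lt(abs(out$group_means["control", "metric_b"]), 0.5)
  expect_error(normalize_profile(m[1, , drop = FALSE]), ">= 2")
})
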