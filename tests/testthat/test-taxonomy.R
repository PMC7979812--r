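test_that("the angle convention is rightward-zero, upward-positive", {
  expect_equal(saccade_angle(10, 0), 0)
  expect_equal(saccade_angle(0, 10), -90)   # downward on screen
  expect_equal(saccade_angle(0, -10), 90)
  expect_equal(saccade_angle(-10, 0), 180)
  expect_true(is.na(saccade_angle(0, 0)))
  # reversing a saccade adds 180 degrees (mod 360, mapped into (-180, 180])
  set.seed(1)
  dx <- rnorm(200); dy <- rnorm(200)
  a <- saccade_angle(dx, dy)
  b <- saccade_angle(-dx, -dy)
  d <- (b - a) %% 360
  expect_true(all(abs(d - 180) < 1e-9))
})

test_that("the classifier matches the brute-force rule evaluator across angles", {
  # moderately dense sweep here; the exhaustive 0.5-degree sweep runs in the
  # acceptance suite
  for (context in c("plain", "blink", "sweep", "undersweep")) {
    amp <- if (context %in% c("sweep", "undersweep")) 600 else 61
    for (theta in seq(-177.5, 180, by = 7.5)) {
      cx <- angle_context(theta, context, amp)
      got <- label_saccades(cx$trial, cx$assignment, cx$layout)$category
      want <- oracle_classify(cx$trial, cx$assignment, cx$layout)
      expect_equal(got, want,
                   info = sprintf("context=%s theta=%.1f", context, theta))
    }
  }
})

test_that("deviation, blink and sweep rules fire on canonical cases", {
  # straight-down saccade mid-line, no blink: directional deviation
  cx <- angle_context(-90, "plain")
  expect_equal(label_saccades(cx$trial, cx$assignment, cx$layout)$category[1],
               "directional_deviation")
  # same saccade with a blink during it: blink-adjacent, not deviation
  cxb <- angle_context(-90, "blink")
  lab <- label_saccades(cxb$trial, cxb$assignment, cxb$layout)$category
  expect_equal(lab[1], "blink_adjacent")
  expect_false(any(lab == "directional_deviation"))

  # line-final word to first word of next line: return sweep
  lay <- make_grid_layout(n_lines = 2, words_per_line = 10)
  w <- lay$words
  go <- function(from, to, extra_x = 80) {
    xs <- c(mean(c(w$x0[from], w$x1[from])), mean(c(w$x0[to], w$x1[to])))
    ys <- c(mean(c(w$y0[from], w$y1[from])), mean(c(w$y0[to], w$y1[to])))
    tr <- make_trial(x = c(xs, xs[2] + extra_x), y = c(ys, ys[2]),
                     dur = rep(180, 3), trial_duration = 5000)
    tr <- derive_saccades(tr)
    label_saccades(tr, assign_fixations(tr, build_interest_areas(lay)),
                   lay)$category[1]
  }
  expect_equal(go(10, 11), "return_sweep")
  # launched from the 4th-from-last word: not a return sweep by the rule
  expect_false(go(7, 11) == "return_sweep")

  # undersweep: last word -> mid next line, then leftward corrective
  xs <- c(mean(c(w$x0[10], w$x1[10])), mean(c(w$x0[16], w$x1[16])),
          mean(c(w$x0[11], w$x1[11])))
  ys <- c(mean(c(w$y0[10], w$y1[10])), mean(c(w$y0[16], w$y1[16])),
          mean(c(w$y0[11], w$y1[11])))
  tr <- derive_saccades(make_trial(x = xs, y = ys, dur = rep(180, 3),
                                   trial_duration = 5000))
  lab <- label_saccades(tr, assign_fixations(tr, build_interest_areas(lay)),
                        lay)$category
  expect_equal(lab[1], "undersweep")
  # same landing, no corrective: not an undersweep
  tr2 <- derive_saccades(make_trial(x = xs[1:2], y = ys[1:2],
                                    dur = rep(180, 2), trial_duration = 5000))
  lab2 <- label_saccades(tr2, assign_fixations(tr2,
                                               build_interest_areas(lay)),
                         lay)$category
  expect_false(lab2[1] == "undersweep")
})

test_that("every saccade gets exactly one category (partition property)", {
  lay <- generate_layout(150, seed = 3)
  areas <- build_interest_areas(lay)
  cats <- c("forward", "regression", "return_sweep", "undersweep",
            "blink_adjacent", "directional_deviation", "other")
  for (s in 1:10) {
    tr <- clean_trial(simulate_trial(lay, dyslexia_profile(),
                                     seed = 400 + s))$trial
    lab <- label_saccades(tr, assign_fixations(tr, areas), lay)
    expect_equal(nrow(lab), nrow(tr$saccades))
    expect_true(all(lab$category %in% cats))
    expect_equal(sum(table(lab$category)), nrow(tr$saccades))
  }
})

test_that("generator-emitted sweeps and undersweeps are recovered (recall 1)", {
  lay <- generate_layout(150, seed = 3)
  areas <- build_interest_areas(lay)
  prof <- dyslexia_profile(); prof$blink_rate <- 0
  for (s in 1:10) {
    tr <- simulate_trial(lay, prof, seed = 600 + s)
    cl <- clean_trial(tr)$trial
    lab <- label_saccades(cl, assign_fixations(cl, areas), lay)
    tt <- tr$truth$transitions
    expect_equal(sum(lab$category == "return_sweep"),
                 sum(tt$type == "sweep" & tt$launch_pos_from_end <= 3))
    expect_equal(sum(lab$category == "undersweep"),
                 sum(tt$type == "undersweep" & tt$launch_pos_from_end <= 4))
  }
})

test_that("line-initial fixations obey the first-two-words/corrective rule", {
  lay <- make_grid_layout(n_lines = 2, words_per_line = 10)
  w <- lay$words
  ctr <- function(i) c(mean(c(w$x0[i], w$x1[i])), mean(c(w$y0[i], w$y1[i])))
  # sweep lands word 1 of line 2, next saccade rightward: line-initial
  p <- rbind(ctr(9), ctr(10), ctr(11), ctr(12))
  tr <- derive_saccades(make_trial(x = p[, 1], y = p[, 2], dur = rep(180, 4),
                                   trial_duration = 6000))
  asg <- assign_fixations(tr, build_interest_areas(lay))
  li <- detect_line_initial(tr, asg, lay)
  expect_true(w$word_index[11] %in% asg$word_index[li$fix])
  # sweep lands word 2, next saccade leftward to word 1: not line-initial
  p2 <- rbind(ctr(9), ctr(10), ctr(12), ctr(11), ctr(13))
  tr2 <- derive_saccades(make_trial(x = p2[, 1], y = p2[, 2],
                                    dur = rep(180, 5), trial_duration = 6000))
  asg2 <- assign_fixations(tr2, build_interest_areas(lay))
  li2 <- detect_line_initial(tr2, asg2, lay)
  expect_false(any(asg2$line_index[li2$fix] == 1))

  # perfect reading: exactly one line-initial fixation per line
  gen <- generate_layout(150, seed = 4)
  prof <- reader_profile(skip_prob = 0, regression_prob = 0,
                         deviation_rate = 0, undersweep_prob = 0,
                         refixation_prob = 0, blink_rate = 0)
  tr3 <- clean_trial(simulate_trial(gen, prof, seed = 2))$trial
  asg3 <- assign_fixations(tr3, build_interest_areas(gen))
  li3 <- detect_line_initial(tr3, asg3, gen)
  expect_equal(nrow(li3), gen$line_count)
  expect_equal(sort(li3$line_index), sort(unique(gen$words$line_index)))
})

test_that("line-initial fixations run longer than the trial median (inflation)", {
  lay <- generate_layout(150, seed = 3)
  areas <- build_interest_areas(lay)
  prof <- dyslexia_profile()   # 32 ms inflation
  diffs <- vapply(1:25, function(s) {
    tr <- clean_trial(simulate_trial(lay, prof, seed = 800 + s))$trial
    asg <- assign_fixations(tr, areas)
    li <- detect_line_initial(tr, asg, lay)
    median(li$duration) - median(tr$fixations$duration)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.7)
})

test_that("polar histograms bin deviations at 2.75 degrees and conserve counts", {
  h0 <- polar_histogram(numeric(0))
  expect_equal(sum(h0$count), 0)
  expect_equal(nrow(h0), 80)        # 40 bins per half-plane
  expect_equal(unique(h0$hi - h0$lo), 2.75)

  h1 <- polar_histogram(rep(-90, 10))
  expect_equal(sum(h1$count), 10)
  expect_equal(sum(h1$count > 0), 1)
  expect_equal(h1$side[h1$count > 0], "down")

  set.seed(9)
  ang <- c(runif(200, 35, 145) * sample(c(-1, 1), 200, TRUE), runif(50, -34, 34))
  h2 <- polar_histogram(ang)
  expect_equal(sum(h2$count), sum(abs(ang) >= 35 & abs(ang) <= 145))

  # group-level directionality: a downward-mode cohort puts its modal bin in
  # the lower half-plane
  lay <- generate_layout(150, seed = 3)
  areas <- build_interest_areas(lay)
  prof <- reader_profile(deviation_rate = 2, deviation_angle_mode = "down")
  angs <- unlist(lapply(1:15, function(s) {
    tr <- clean_trial(simulate_trial(lay, prof, seed = 900 + s))$trial
    lab <- label_saccades(tr, assign_fixations(tr, areas), lay)
    lab$angle[lab$category == "directional_deviation"]
  }))
  hd <- polar_histogram(angs)
  expect_equal(hd$side[which.max(hd$count)], "down")
  expect_gt(sum(hd$count[hd$side == "down"]), sum(hd$count[hd$side == "up"]))
})
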