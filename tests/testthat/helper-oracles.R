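# Independent brute-force oracles. These re-derive expected values from
# first principles, deliberately sharing no code with the implementation.

# --- saccade classification: literal transcription of the rule book -------
oracle_classify <- function(trial, assignment, layout, bounds = c(35, 145)) {
  sc <- trial$saccades
  fx <- trial$fixations
  bl <- trial$blinks
  w <- layout$words
  rank_in_line <- integer(nrow(w))
  line_size <- integer(0)
  for (li in unique(w$line_index)) {
    sel <- w$line_index == li
    rank_in_line[sel] <- seq_len(sum(sel))
    line_size[as.character(li)] <- sum(sel)
  }
  rank_of <- function(word) rank_in_line[which(w$word_index == word)]

  out <- character(nrow(sc))
  for (k in seq_len(nrow(sc))) {
    f1 <- sc$from_fix[k]; f2 <- sc$to_fix[k]
    # blink immediately before / during / after: any blink inside the time
    # window from the end of the previous-but-one fixation to the start of
    # the next-but-one fixation (blinks live in inter-fixation gaps)
    w0 <- if (f1 > 1) fx$offset[f1 - 1] else fx$onset[f1]
    w1 <- if (f2 < nrow(fx)) fx$onset[f2 + 1] else fx$offset[f2]
    blink <- nrow(bl) > 0 && any(bl$onset < w1 & bl$offset > w0)

    dx <- sc$x1[k] - sc$x0[k]; dy <- sc$y1[k] - sc$y0[k]
    ang <- if (dx == 0 && dy == 0) NA_real_ else {
      a <- atan2(-dy, dx) * 180 / pi
      if (a <= -180) a + 360 else a
    }
    lw <- assignment$word_index[f1]; dw <- assignment$word_index[f2]
    ll <- assignment$line_index[f1]; dl <- assignment$line_index[f2]

    rs <- us <- FALSE
    if (!is.na(lw) && !is.na(dw) && !is.na(ll) && !is.na(dl) &&
        dl == ll + 1) {
      nlast <- line_size[as.character(ll)] - rank_of(lw)  # 0 = final word
      if (nlast <= 2 && rank_of(dw) <= 3) rs <- TRUE
      if (!rs && nlast <= 3 && rank_of(dw) > 3) {
        nxt <- which(sc$from_fix == f2)
        if (length(nxt)) {
          nxt <- nxt[1]
          land_line <- assignment$line_index[sc$to_fix[nxt]]
          if (sc$x1[nxt] < sc$x0[nxt] && !is.na(land_line) &&
              land_line == dl)
            us <- TRUE
        }
      }
    }
    dev <- !is.na(ang) && abs(ang) >= bounds[1] && abs(ang) <= bounds[2]

    visited_before <- assignment$word_index[seq_len(f1)]
    visited_before <- visited_before[!is.na(visited_before)]
    frontier <- if (length(visited_before)) max(visited_before) else -1
    reg <- !is.na(lw) && !is.na(dw) && dw < lw && dw <= frontier

    out[k] <-
      if (blink) "blink_adjacent"
      else if (rs) "return_sweep"
      else if (us) "undersweep"
      else if (dev) "directional_deviation"
      else if (reg) "regression"
      else if (!is.na(lw) && !is.na(dw) && dw >= lw) "forward"
      else if ((is.na(lw) || is.na(dw)) && !is.na(ang) &&
                 abs(ang) < bounds[1] && dx > 0) "forward"
      else "other"
  }
  out
}

# --- scasim: exhaustive enumeration over all alignments -------------------
oracle_scasim <- function(a, b, modulator = 0.83, geometry = default_geom) {
  subcost <- function(i, j) {
    d <- px_to_deg(sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2), geometry)
    a$duration[i] + b$duration[j] -
      2 * min(a$duration[i], b$duration[j]) * modulator^d
  }
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- Inf
    if (i > 0) best <- min(best, rec(i - 1, j) + a$duration[i])
    if (j > 0) best <- min(best, rec(i, j - 1) + b$duration[j])
    if (i > 0 && j > 0) best <- min(best, rec(i - 1, j - 1) + subcost(i, j))
    best
  }
  rec(nrow(a), nrow(b))
}

# --- trial metrics recomputed from raw event lists ------------------------
# own interest-area construction + point-in-box assignment + frontier walk
oracle_metrics <- function(trial, layout, padding = 5) {
  w <- layout$words
  fx <- trial$fixations
  # padded, gap-filled, line-unified areas
  word_of_fix <- rep(NA_integer_, nrow(fx))
  for (li in unique(w$line_index)) {
    lw <- w[w$line_index == li, ]
    lw <- lw[order(lw$x0), ]
    ytop <- min(lw$y0) - padding; ybot <- max(lw$y1) + padding
    lo <- lw$x0 - padding; hi <- lw$x1 + padding
    if (nrow(lw) > 1) {
      for (k in seq_len(nrow(lw) - 1)) {
        mid <- (hi[k] + lo[k + 1]) / 2
        hi[k] <- mid; lo[k + 1] <- mid
      }
    }
    for (i in seq_len(nrow(fx))) {
      if (is.na(word_of_fix[i]) && fx$y[i] >= ytop && fx$y[i] <= ybot) {
        for (k in seq_len(nrow(lw))) {
          inside <- if (k == 1) fx$x[i] >= lo[k] && fx$x[i] <= hi[k]
                    else fx$x[i] > lo[k] && fx$x[i] <= hi[k]
          if (inside) { word_of_fix[i] <- lw$word_index[k]; break }
        }
      }
    }
  }
  seq_w <- word_of_fix[!is.na(word_of_fix)]
  seq_d <- fx$duration[!is.na(word_of_fix)]
  first_run <- setNames(numeric(nrow(w)), w$word_index)
  nfix <- setNames(integer(nrow(w)), w$word_index)
  skipped <- setNames(logical(nrow(w)), w$word_index)
  visited <- setNames(logical(nrow(w)), w$word_index)
  frontier <- -1
  run_open <- NA
  for (k in seq_along(seq_w)) {
    wd <- seq_w[k]; key <- as.character(wd)
    nfix[key] <- nfix[key] + 1L
    visited[key] <- TRUE
    if (wd > frontier) {
      for (z in w$word_index)
        if (z > frontier && z < wd && !visited[as.character(z)])
          skipped[as.character(z)] <- TRUE
      frontier <- wd
      run_open <- wd
      first_run[key] <- seq_d[k]
    } else if (!is.na(run_open) && wd == run_open && !skipped[key]) {
      first_run[key] <- first_run[key] + seq_d[k]
    } else run_open <- NA
  }
  amp <- trial$saccades$amplitude
  list(mean_fixdur = mean(fx$duration),
       median_fixdur = median(fx$duration),
       total_scanpath = sum(amp),
       median_sacc_amp = median(amp),
       first_run_dwell_time = sum(first_run) / 1000,
       ratio_first_run_words_skipped = mean(skipped),
       ratio_visited_words = mean(visited),
       fixations_per_word = sum(nfix) / nrow(w),
       wpm = nrow(w) / (trial$trial_duration / 60000),
       word_of_fix = word_of_fix)
}
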