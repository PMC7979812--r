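#' Saccade angle under the reading convention
#'
#' Angle in degrees in (-180, 180], with 0 the horizontal rightward reading
#' direction and positive angles upward. Screen y grows downward, so the
#' vertical displacement is negated: `atan2(-dy, dx)`.
#'
#' @param dx,dy pixel displacements (vectorised).
#' @return angle in degrees; `NA` for zero displacement.
#' @export
saccade_angle <- function(dx, dy) {
  a <- atan2(-dy, dx) * 180 / pi
  a[a <= -180] <- a[a <= -180] + 360
  a[dx == 0 & dy == 0] <- NA_real_
  a
}

#' Classify saccades into reading categories
#'
#' Assigns each derived saccade exactly one category with precedence
#' blink-adjacent > return-sweep > undersweep > directional deviation >
#' regression > forward > other:
#' \itemize{
#' \item \strong{blink_adjacent}: a blink falls within this saccade's time
#'   span or within the immediately preceding/following inter-fixation gap.
#' \item \strong{return_sweep}: launched from one of the last 3 words of a
#'   line and landing on one of the first 3 words of the next line.
#' \item \strong{undersweep}: launched from one of the last 4 words of a
#'   line, landing on the next line beyond its first 3 words, and followed by
#'   a leftward saccade within that line (the corrective).
#' \item \strong{directional_deviation}: `|angle|` within
#'   `deviation_bounds` (inclusive; default 35-145 degrees).
#' \item \strong{regression}: leftward in word order to a previously visited
#'   or skipped word.
#' \item \strong{forward}: word order non-decreasing, or unassigned but
#'   within 35 degrees of the rightward reading direction.
#' }
#'
#' @param trial a cleaned `trial_record` (saccades from [derive_saccades()]).
#' @param assignment fixation-to-word assignment from [assign_fixations()].
#' @param layout the `text_layout` (for words-per-line ranks).
#' @param deviation_bounds inclusive `c(lower, upper)` bounds on `|angle|`.
#' @return data.frame, one row per saccade: `angle`, `amplitude`,
#'   `launch_word`, `landing_word`, `launch_line`, `landing_line`,
#'   `category`.
#' @export
label_saccades <- function(trial, assignment, layout,
                           deviation_bounds = c(35, 145)) {
  sc <- trial$saccades
  fx <- trial$fixations
  bl <- trial$blinks
  n <- nrow(sc)
  out <- data.frame(angle = numeric(n), amplitude = numeric(n),
                    launch_word = integer(n), landing_word = integer(n),
                    launch_line = integer(n), landing_line = integer(n),
                    category = character(n))
  if (!n) return(out)

  w <- layout$words
  pos_in_line <- stats::ave(rep(1, nrow(w)), w$line_index, FUN = seq_along)
  nl_of_line <- table(w$line_index)
  word_pos <- function(wi) pos_in_line[match(wi, w$word_index)]
  line_n <- function(li) as.integer(nl_of_line[as.character(li)])

  out$angle <- saccade_angle(sc$x1 - sc$x0, sc$y1 - sc$y0)
  out$amplitude <- sc$amplitude
  out$launch_word <- assignment$word_index[sc$from_fix]
  out$landing_word <- assignment$word_index[sc$to_fix]
  out$launch_line <- assignment$line_index[sc$from_fix]
  out$landing_line <- assignment$line_index[sc$to_fix]

  # blink presence per inter-fixation gap (indexed by the earlier fixation)
  gap_blink <- rep(FALSE, max(1, nrow(fx) - 1))
  if (nrow(bl) && nrow(fx) > 1) {
    for (g in seq_len(nrow(fx) - 1)) {
      gap_blink[g] <- any(bl$onset < fx$onset[g + 1] &
                            bl$offset > fx$offset[g])
    }
  }

  # frontier (max word index) before each saccade, for the regression rule
  word_seq <- assignment$word_index
  frontier_before <- vapply(seq_len(n), function(k) {
    prev <- word_seq[seq_len(sc$from_fix[k])]
    if (all(is.na(prev))) -1L else max(prev, na.rm = TRUE)
  }, integer(1))

  lo <- deviation_bounds[1]; hi <- deviation_bounds[2]
  for (k in seq_len(n)) {
    g <- sc$from_fix[k]
    blinky <- any(gap_blink[intersect(c(g - 1L, g, g + 1L),
                                      seq_along(gap_blink))])
    lw <- out$launch_word[k]; dw <- out$landing_word[k]
    ll <- out$launch_line[k]; dl <- out$landing_line[k]
    have_words <- !is.na(lw) && !is.na(dw)
    rs <- us <- FALSE
    if (have_words && !is.na(ll) && !is.na(dl) && dl == ll + 1L) {
      launch_from_end <- line_n(ll) - word_pos(lw) + 1L
      landing_pos <- word_pos(dw)
      rs <- launch_from_end <= 3L && landing_pos <= 3L
      if (!rs && launch_from_end <= 4L && landing_pos > 3L) {
        # corrective: next saccade leftward, landing on the same (new) line
        nk <- which(sc$from_fix == sc$to_fix[k])
        us <- length(nk) > 0 &&
          (sc$x1[nk[1]] < sc$x0[nk[1]]) &&
          !is.na(out$landing_line[nk[1]]) && out$landing_line[nk[1]] == dl
      }
    }
    ang <- out$angle[k]
    dev <- !is.na(ang) && abs(ang) >= lo && abs(ang) <= hi
    cat <- if (blinky) "blink_adjacent"
    else if (rs) "return_sweep"
    else if (us) "undersweep"
    else if (dev) "directional_deviation"
    else if (have_words && dw < lw && dw <= frontier_before[k]) "regression"
    else if (have_words && dw >= lw) "forward"
    else if (!have_words && !is.na(ang) && abs(ang) < lo &&
               sc$x1[k] > sc$x0[k]) "forward"
    else "other"
    out$category[k] <- cat
  }
  out
}

#' Detect line-initial fixations
#'
#' For each line, the temporally first fixation landing on one of the line's
#' first two words qualifies as line-initial unless the next saccade moves
#' leftward of it within the same line (an undersweep corrective). At most
#' one line-initial fixation per line.
#'
#' @param trial a cleaned `trial_record`.
#' @param assignment from [assign_fixations()].
#' @param layout the `text_layout`.
#' @return data.frame: `fix`, `line_index`, `duration`.
#' @export
detect_line_initial <- function(trial, assignment, layout) {
  fx <- trial$fixations
  sc <- trial$saccades
  w <- layout$words
  pos_in_line <- stats::ave(rep(1, nrow(w)), w$line_index, FUN = seq_along)
  res <- list()
  for (li in sort(unique(w$line_index))) {
    cand <- which(!is.na(assignment$word_index) &
                    assignment$line_index == li &
                    pos_in_line[match(assignment$word_index,
                                      w$word_index)] <= 2)
    if (!length(cand)) next
    f <- cand[1]
    nk <- which(sc$from_fix == f)
    disqualified <- length(nk) > 0 &&
      sc$x1[nk[1]] < fx$x[f] &&
      !is.na(assignment$line_index[sc$to_fix[nk[1]]]) &&
      assignment$line_index[sc$to_fix[nk[1]]] == li
    if (!disqualified)
      res[[length(res) + 1]] <- data.frame(fix = f, line_index = li,
                                           duration = fx$duration[f])
  }
  if (!length(res))
    return(data.frame(fix = integer(0), line_index = integer(0),
                      duration = numeric(0)))
  do.call(rbind, res)
}

#' Polar histogram of directional-deviation angles
#'
#' Counts deviation angles in bins of `bin_width` degrees covering the two
#' qualifying bands (by default 35 to 145 degrees above and below the
#' reading axis; 110/2.75 = 40 bins per band). Only directional deviations
#' are counted; the counts sum to the number of deviations.
#'
#' @param angles deviation angles in degrees (convention of
#'   [saccade_angle()]).
#' @param bin_width bin width in degrees.
#' @param bounds inclusive `c(lower, upper)` magnitude bounds.
#' @return data.frame: `side` ("up"/"down"), `lo`, `hi`, `count`.
#' @export
polar_histogram <- function(angles, bin_width = 2.75, bounds = c(35, 145)) {
  edges <- seq(bounds[1], bounds[2], by = bin_width)
  if (abs(edges[length(edges)] - bounds[2]) > 1e-9)
    stop("bin_width must divide the band width")
  nb <- length(edges) - 1
  grid <- data.frame(side = rep(c("up", "down"), each = nb),
                     lo = rep(edges[-length(edges)], 2),
                     hi = rep(edges[-1], 2), count = 0L)
  ok <- !is.na(angles) & abs(angles) >= bounds[1] & abs(angles) <= bounds[2]
  for (a in angles[ok]) {
    side <- if (a > 0) "up" else "down"
    b <- min(nb, max(1, ceiling((abs(a) - bounds[1]) / bin_width)))
    i <- which(grid$side == side)[b]
    grid$count[i] <- grid$count[i] + 1L
  }
  grid
}
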