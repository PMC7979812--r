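#' Build word-based interest areas
#'
#' Expands each word's bounding box by `padding_px` on all sides, unifies the
#' vertical extent of all areas on a line to the line's union extent, and
#' closes residual horizontal gaps between adjacent words by splitting them
#' at the midpoint, so each line is fully tiled.
#'
#' @param layout a `text_layout`.
#' @param padding_px padding in pixels (default 5).
#' @return data.frame with `word_index`, `line_index`, `x0`, `x1`, `y0`,
#'   `y1`: contiguous, non-overlapping areas per line.
#' @export
build_interest_areas <- function(layout, padding_px = 5) {
  validate_layout(layout)
  w <- layout$words
  ia <- data.frame(word_index = w$word_index, line_index = w$line_index,
                   x0 = w$x0 - padding_px, x1 = w$x1 + padding_px,
                   y0 = w$y0 - padding_px, y1 = w$y1 + padding_px)
  for (li in unique(ia$line_index)) {
    sel <- which(ia$line_index == li)
    ia$y0[sel] <- min(ia$y0[sel])
    ia$y1[sel] <- max(ia$y1[sel])
    if (length(sel) > 1) {
      for (k in seq_len(length(sel) - 1)) {
        a <- sel[k]; b <- sel[k + 1]
        mid <- (ia$x1[a] + ia$x0[b]) / 2
        ia$x1[a] <- mid
        ia$x0[b] <- mid
      }
    }
  }
  ia
}

#' Assign fixations to words
#'
#' Point-in-rectangle assignment of each fixation to an interest area.
#' Shared boundaries belong to the left (and upper) area. Fixations outside
#' every area get `NA` word and line.
#'
#' @param trial a `trial_record`.
#' @param areas interest areas from [build_interest_areas()].
#' @return data.frame with one row per fixation: `fix`, `word_index`,
#'   `line_index`, `in_ia`.
#' @export
assign_fixations <- function(trial, areas) {
  fx <- trial$fixations
  lines <- unique(areas$line_index)
  band <- do.call(rbind, lapply(lines, function(li) {
    a <- areas[areas$line_index == li, ]
    data.frame(line_index = li, y0 = a$y0[1], y1 = a$y1[1])
  }))
  word <- rep(NA_integer_, nrow(fx))
  line <- rep(NA_integer_, nrow(fx))
  for (i in seq_len(nrow(fx))) {
    hit <- which(fx$y[i] >= band$y0 & fx$y[i] <= band$y1)
    if (!length(hit)) next
    li <- band$line_index[hit[1]]           # upper band wins a shared edge
    a <- areas[areas$line_index == li, ]
    a <- a[order(a$x0), ]
    edges <- c(a$x0[1], a$x1)
    x <- fx$x[i]
    if (x < edges[1] || x > edges[length(edges)]) next
    k <- findInterval(x, edges, left.open = TRUE)  # (e[k], e[k+1]] -> area k
    if (k == 0) k <- 1                             # left-most edge itself
    word[i] <- a$word_index[k]
    line[i] <- li
  }
  data.frame(fix = seq_len(nrow(fx)), word_index = word, line_index = line,
             in_ia = !is.na(word))
}

#' Correct a uniform vertical drift
#'
#' Searches integer vertical shifts within +/- half the line spacing and
#' applies, to all fixations of the trial at once, the shift that maximizes
#' a centrality-weighted count of fixations inside interest areas (full
#' weight at a band's vertical centre, zero at its edge). Horizontal
#' coordinates are never changed and fixations are never moved individually.
#' Ties prefer the smallest absolute shift (then the smaller shift).
#'
#' @param trial a cleaned `trial_record`.
#' @param areas interest areas from [build_interest_areas()].
#' @param mode `"off"` (identity) or `"global_shift"`.
#' @return `list(trial, applied_shift_px)`.
#' @export
correct_vertical_drift <- function(trial, areas,
                                   mode = c("off", "global_shift")) {
  mode <- match.arg(mode)
  if (mode == "off" || !nrow(trial$fixations))
    return(list(trial = trial, applied_shift_px = 0L))
  bands <- unique(areas[, c("line_index", "y0", "y1")])
  spacing <- if (nrow(bands) > 1)
    median(diff(sort((bands$y0 + bands$y1) / 2))) else bands$y1[1] - bands$y0[1]
  half <- max(1L, floor(spacing / 2))
  shifts <- (-half):half
  # centrality-weighted in-area count: a fixation scores 1 at its band's
  # vertical centre, falling linearly to 0 at the band edge. A raw count is
  # piecewise constant in the shift (every shift on a plateau ties); the
  # triangular weight makes the optimum unique and robust to stray
  # between-line fixations being captured by a neighbouring band.
  score <- vapply(shifts, function(s) {
    y <- trial$fixations$y + s
    sc <- 0
    for (b in seq_len(nrow(bands))) {
      inb <- y >= bands$y0[b] & y <= bands$y1[b]
      ctr <- (bands$y0[b] + bands$y1[b]) / 2
      hh <- (bands$y1[b] - bands$y0[b]) / 2
      sc <- sc + sum(1 - abs(y[inb] - ctr) / hh)
    }
    sc
  }, numeric(1))
  best <- shifts[abs(score - max(score)) < 1e-9]
  shift <- best[order(abs(best), best)][1]
  trial$fixations$y <- trial$fixations$y + shift
  if (nrow(trial$saccades)) {
    trial$saccades$y0 <- trial$saccades$y0 + shift
    trial$saccades$y1 <- trial$saccades$y1 + shift
  }
  list(trial = trial, applied_shift_px = as.integer(shift))
}
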