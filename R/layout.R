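#' Generate a multi-line left-aligned text layout
#'
#' Produces per-word bounding boxes for a paragraph laid out on a fixed-width
#' character grid, emulating ~150-word standardized reading texts with ~84
#' characters per line. Word lengths are drawn from a truncated
#' Poisson(`word_lambda`) + 1 distribution (truncated at `max_word_chars` so
#' every word fits a line).
#'
#' Coordinates are 0-based screen pixels, origin top-left, y increasing
#' downward.
#'
#' @param n_words number of words (>= 1).
#' @param chars_per_line line width in characters.
#' @param char_px horizontal pixel width of one character.
#' @param line_spacing_px baseline-to-baseline distance between lines.
#' @param seed integer seed; layouts are deterministic given the seed.
#' @param word_lambda Poisson rate for word length minus one.
#' @param max_word_chars truncation point of the word-length distribution.
#' @param char_height_px height of a word's bounding box.
#' @param margin_x,margin_y top-left corner of the text block.
#' @param geometry a [display_geometry()]; boxes must fit the display.
#' @return a `text_layout`: list with `words` (data.frame `word_index`,
#'   `line_index`, `x0`, `y0`, `x1`, `y1`, `char_count`; word and line indices
#'   0-based), `line_count`, `line_spacing_px`, `char_px` and
#'   `display_bounds`.
#' @export
generate_layout <- function(n_words, chars_per_line = 84, char_px = 11,
                            line_spacing_px = 55, seed = 1L,
                            word_lambda = 4, max_word_chars = 12,
                            char_height_px = 19,
                            margin_x = 30, margin_y = 60,
                            geometry = display_geometry()) {
  if (n_words < 1) stop("n_words must be >= 1")
  if (chars_per_line <= 0 || char_px <= 0 || line_spacing_px <= 0 ||
      char_height_px <= 0)
    stop("geometry parameters must be positive")
  if (chars_per_line < max_word_chars)
    stop("chars_per_line must be at least max_word_chars")
  set.seed(as.integer(seed))
  lens <- rpois(n_words, word_lambda)
  while (any(lens > max_word_chars - 1))  # truncate the tail by redrawing
    lens[lens > max_word_chars - 1] <- rpois(sum(lens > max_word_chars - 1),
                                             word_lambda)
  lens <- lens + 1L

  line <- integer(n_words); colchar <- numeric(n_words)
  cur_line <- 0L; cursor <- 0
  for (i in seq_len(n_words)) {
    need <- lens[i] + (cursor > 0)  # leading inter-word gap unless line start
    if (cursor + need > chars_per_line) {
      cur_line <- cur_line + 1L
      cursor <- 0
      need <- lens[i]
    }
    line[i] <- cur_line
    colchar[i] <- cursor + (need - lens[i])
    cursor <- cursor + need
  }
  x0 <- margin_x + colchar * char_px
  x1 <- x0 + lens * char_px
  y0 <- margin_y + line * line_spacing_px
  y1 <- y0 + char_height_px
  if (max(x1) > geometry$width_px || max(y1) > geometry$height_px)
    stop("layout exceeds display bounds; reduce n_words or spacing")
  words <- data.frame(word_index = seq_len(n_words) - 1L,
                      line_index = line,
                      x0 = x0, y0 = y0, x1 = x1, y1 = y1,
                      char_count = lens)
  layout <- structure(list(words = words,
                           line_count = cur_line + 1L,
                           line_spacing_px = line_spacing_px,
                           char_px = char_px,
                           display_bounds = c(0, 0, geometry$width_px,
                                              geometry$height_px)),
                      class = "text_layout")
  validate_layout(layout)
  layout
}

#' Validate text-layout invariants
#'
#' Checks reading-order word indices, non-overlapping increasing x-extents
#' within each line, non-decreasing line indices, and containment in the
#' display bounds.
#'
#' @param layout a `text_layout`.
#' @return the layout, invisibly; errors if an invariant is violated.
#' @export
validate_layout <- function(layout) {
  w <- layout$words
  if (any(diff(w$word_index) != 1L))
    stop("word indices must increase in reading order")
  if (any(diff(w$line_index) < 0L))
    stop("line indices must be non-decreasing with word index")
  if (any(w$x0 >= w$x1) || any(w$y0 >= w$y1) || any(w$char_count < 1))
    stop("degenerate word box")
  for (li in unique(w$line_index)) {
    lw <- w[w$line_index == li, ]
    if (nrow(lw) > 1 && any(lw$x0[-1] < lw$x1[-nrow(lw)]))
      stop("overlapping word boxes within a line")
  }
  b <- layout$display_bounds
  if (any(w$x0 < b[1]) || any(w$y0 < b[2]) ||
      any(w$x1 > b[3]) || any(w$y1 > b[4]))
    stop("word box outside display bounds")
  invisible(layout)
}

# words of one line in reading order, with within-line rank
.line_words <- function(layout, li) {
  lw <- layout$words[layout$words$line_index == li, ]
  lw$line_pos <- seq_len(nrow(lw))
  lw
}
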