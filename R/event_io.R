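#' Write trials to a tab-separated event report
#'
#' One row per event (fixation, saccade, blink), UTF-8, locale-independent
#' numbers, deterministic column order: participant, group, font, text,
#' trial, event_type, onset, offset, x0, y0, x1, y1, duration,
#' trial_duration. Fixations carry their position in `x0`/`y0` and their
#' (possibly merge-summed) duration in `duration`; blinks carry only times.
#' Timestamps are trial-relative milliseconds; coordinates 0-based pixels,
#' origin top-left, y downward.
#'
#' @param trials a list of `trial_record`s.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_event_report <- function(trials, path) {
  cols <- c("participant", "group", "font", "text", "trial", "event_type",
            "onset", "offset", "x0", "y0", "x1", "y1", "duration",
            "trial_duration")
  rows <- lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    base <- data.frame(participant = tr$participant_id, group = tr$group,
                       font = tr$font, text = tr$text_id, trial = i,
                       stringsAsFactors = FALSE)
    fx <- tr$fixations; sc <- tr$saccades; bl <- tr$blinks
    out <- rbind(
      if (nrow(fx)) cbind(base, event_type = "fixation", onset = fx$onset,
                          offset = fx$offset, x0 = fx$x, y0 = fx$y,
                          x1 = NA_real_, y1 = NA_real_,
                          duration = fx$duration),
      if (nrow(sc)) cbind(base, event_type = "saccade", onset = sc$onset,
                          offset = sc$offset, x0 = sc$x0, y0 = sc$y0,
                          x1 = sc$x1, y1 = sc$y1, duration = NA_real_),
      if (nrow(bl)) cbind(base, event_type = "blink", onset = bl$onset,
                          offset = bl$offset, x0 = NA_real_, y0 = NA_real_,
                          x1 = NA_real_, y1 = NA_real_, duration = NA_real_))
    if (is.null(out)) out <- cbind(base[0, ], event_type = character(0),
                                   onset = numeric(0), offset = numeric(0),
                                   x0 = numeric(0), y0 = numeric(0),
                                   x1 = numeric(0), y1 = numeric(0),
                                   duration = numeric(0))
    out <- out[order(out$onset), ]
    out$trial_duration <- tr$trial_duration
    out
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
  tab <- tab[, cols]
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a tab-separated event report
#'
#' Parses the dialect written by [write_event_report()] into one
#' `trial_record` per (participant, text, font). Events are sorted by onset;
#' unsorted input is repaired with a warning, or rejected when
#' `strict = TRUE`.
#'
#' @param path input file.
#' @param geometry a [display_geometry()] attached to every trial (the
#'   report stores events only).
#' @param strict error (rather than warn) on unsorted timestamps.
#' @return list of `trial_record`s.
#' @export
read_event_report <- function(path, geometry = display_geometry(),
                              strict = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8")
  needed <- c("participant", "group", "font", "text", "event_type",
              "onset", "offset", "x0", "y0", "x1", "y1", "duration",
              "trial_duration")
  missing <- setdiff(needed, names(tab))
  if (length(missing))
    stop("format error: missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  bad <- which(!is.finite(tab$onset) | !is.finite(tab$offset) |
                 tab$offset <= tab$onset)
  if (length(bad))
    stop("malformed event rows (offset <= onset or non-numeric) at line(s): ",
         paste(utils::head(bad + 1L, 10), collapse = ", "))
  key <- paste(tab$participant, tab$text, tab$font, sep = "\r")
  lapply(split(tab, factor(key, levels = unique(key))), function(d) {
    if (is.unsorted(d$onset)) {
      msg <- sprintf("unsorted timestamps for %s/%s/%s",
                     d$participant[1], d$text[1], d$font[1])
      if (strict) stop(msg) else warning(msg, "; repaired by sorting")
      d <- d[order(d$onset), ]
    }
    fx <- d[d$event_type == "fixation", ]
    sc <- d[d$event_type == "saccade", ]
    bl <- d[d$event_type == "blink", ]
    structure(list(participant_id = d$participant[1], group = d$group[1],
                   font = d$font[1], text_id = d$text[1],
                   fixations = data.frame(onset = fx$onset, offset = fx$offset,
                                          x = fx$x0, y = fx$y0,
                                          duration = fx$duration),
                   saccades = data.frame(onset = sc$onset, offset = sc$offset,
                                         x0 = sc$x0, y0 = sc$y0,
                                         x1 = sc$x1, y1 = sc$y1,
                                         amplitude = rep(NA_real_, nrow(sc))),
                   blinks = data.frame(onset = bl$onset, offset = bl$offset),
                   geometry = geometry,
                   trial_duration = d$trial_duration[1],
                   truth = NULL),
              class = "trial_record")
  })
}
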