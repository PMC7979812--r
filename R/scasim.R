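#' Scasim configuration
#'
#' @param modulator per-degree decay of the duration credit for spatially
#'   mismatched fixations, in (0, 1). The default 0.83 halves the credit
#'   roughly every 3.7 degrees.
#' @param normalize divide each pairwise score by the summed total fixation
#'   duration of the two trials, giving a unitless fraction interpretable as
#'   the proportion of viewing time spent dissimilarly.
#' @param geometry a [display_geometry()] for the pixel-to-degree
#'   conversion.
#' @return an object of class `scasim_config`.
#' @export
scasim_config <- function(modulator = 0.83, normalize = TRUE,
                          geometry = display_geometry()) {
  if (!is.finite(modulator) || modulator <= 0 || modulator >= 1)
    stop("modulator must lie strictly between 0 and 1")
  structure(list(modulator = modulator, normalize = normalize,
                 geometry = geometry), class = "scasim_config")
}

#' Scasim dissimilarity of two scanpaths
#'
#' Global sequence alignment of two fixation sequences by dynamic
#' programming. Deleting or inserting a fixation costs its duration;
#' substituting fixations a and b costs
#' `dur_a + dur_b - 2 * min(dur_a, dur_b) * modulator^d(a,b)` where `d` is
#' the angular distance (degrees of visual angle) between their positions.
#' Identical scanpaths score 0; a scanpath against an empty one scores its
#' total duration. The raw score is in milliseconds.
#'
#' @param a,b scanpaths: data.frames with columns `x`, `y` (px) and
#'   `duration` (ms), time-ordered.
#' @param config a [scasim_config()] (normalization is *not* applied here;
#'   see [scasim_matrix()]).
#' @return dissimilarity in ms.
#' @export
scasim_pair <- function(a, b, config = scasim_config()) {
  stopifnot(inherits(config, "scasim_config"))
  if (!nrow(a) && !nrow(b)) return(0)
  g <- config$geometry
  scasim_pair_cpp(as.numeric(a$x), as.numeric(a$y), as.numeric(a$duration),
                  as.numeric(b$x), as.numeric(b$y), as.numeric(b$duration),
                  config$modulator, g$px_size_mm, g$viewing_distance_mm)
}

#' Pairwise Scasim matrix for trials of one text-font pair
#'
#' Computes all pairwise dissimilarities between the (cleaned) fixation
#' sequences of trials sharing the same text and font. With
#' `config$normalize` each score is divided by the summed total fixation
#' duration of the two trials.
#'
#' @param trials list of `trial_record`s, all with identical `text_id` and
#'   `font`.
#' @param config a [scasim_config()].
#' @return symmetric matrix with zero diagonal; attributes `normalized` and
#'   `groups` (per-trial group labels).
#' @export
scasim_matrix <- function(trials, config = scasim_config()) {
  if (length(trials) < 2) stop("need >= 2 trials")
  txt <- vapply(trials, `[[`, "", "text_id")
  fnt <- vapply(trials, `[[`, "", "font")
  if (length(unique(txt)) > 1 || length(unique(fnt)) > 1)
    stop("grouping error: trials mix texts or fonts")
  paths <- lapply(trials, function(tr)
    tr$fixations[, c("x", "y", "duration")])
  totdur <- vapply(paths, function(p) sum(p$duration), numeric(1))
  n <- length(paths)
  M <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- scasim_pair(paths[[i]], paths[[j]], config)
      if (config$normalize) s <- s / (totdur[i] + totdur[j])
      M[i, j] <- M[j, i] <- s
    }
  }
  dimnames(M) <- list(vapply(trials, `[[`, "", "participant_id"),
                      vapply(trials, `[[`, "", "participant_id"))
  attr(M, "normalized") <- config$normalize
  attr(M, "groups") <- vapply(trials, `[[`, "", "group")
  M
}
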