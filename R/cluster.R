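#' Embed a dissimilarity matrix and cluster trials
#'
#' Mirrors the dist -> isoMDS -> mclustBIC -> kmeans sequence: Euclidean
#' re-distancing of the dissimilarity matrix rows, non-metric
#' multidimensional scaling to 2-D, Gaussian-mixture BIC over k = 1..`k_max`
#' on the embedded coordinates to pick the number of clusters, then k-means
#' with that k (fixed seed, `nstart` restarts). The double distancing
#' (Euclidean distances between rows of an already-dissimilarity matrix) is
#' deliberate; set `direct = TRUE` to scale the dissimilarities themselves.
#'
#' @param M symmetric dissimilarity matrix (e.g. from [scasim_matrix()]).
#' @param k_max largest cluster count considered (additionally capped at a
#'   third of the trial count, so clusters keep at least ~3 trials each).
#' @param nstart k-means restarts.
#' @param seed seed for the stochastic steps.
#' @param direct skip the Euclidean re-distancing.
#' @return list: `points` (n x 2), `k`, `assignments`, `stress` (percent),
#'   `degenerate` (TRUE when all trials coincide and k = 1 is forced).
#' @export
embed_and_cluster <- function(M, k_max = 9, nstart = 50, seed = 1L,
                              direct = FALSE) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  if (nrow(M) < 4) stop("need >= 4 trials")
  set.seed(as.integer(seed))
  d <- if (direct) stats::as.dist(M) else dist(M)
  if (all(d < 1e-12)) {
    return(list(points = matrix(0, nrow(M), 2), k = 1L,
                assignments = rep(1L, nrow(M)), stress = 0,
                degenerate = TRUE))
  }
  d[d < 1e-9] <- 1e-9           # isoMDS rejects zero distances
  mds <- MASS::isoMDS(d, k = 2, trace = FALSE)
  pts <- mds$points
  # cap the mixture search so clusters keep >= 3 trials on average
  g_hi <- max(1, min(k_max, nrow(pts) - 1, floor(nrow(pts) / 3)))
  bic <- mclust::mclustBIC(pts, G = 1:g_hi, verbose = FALSE)
  ks <- as.integer(rownames(bic))
  best_k <- ks[which(bic == max(bic, na.rm = TRUE), arr.ind = TRUE)[1]]
  if (best_k == 1L) {
    return(list(points = pts, k = 1L, assignments = rep(1L, nrow(pts)),
                stress = mds$stress, degenerate = TRUE))
  }
  km <- kmeans(pts, centers = best_k, nstart = nstart)
  list(points = pts, k = best_k, assignments = km$cluster,
       stress = mds$stress, degenerate = FALSE)
}

#' Cluster-group association test
#'
#' Builds the k x 2 contingency table of cluster membership against
#' experimental group and tests association with a chi-square test when all
#' expected counts are at least 5, a Fisher exact test otherwise.
#'
#' @param assignments integer cluster per trial.
#' @param groups group label per trial (two levels).
#' @return list: `table`, `method` ("chisq", "fisher" or "undefined" for a
#'   single cluster), `statistic` (`NA` for Fisher), `p`.
#' @export
association_test <- function(assignments, groups) {
  stopifnot(length(assignments) == length(groups))
  tab <- table(cluster = assignments, group = groups)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    return(list(table = tab, method = "undefined", statistic = NA_real_,
                p = NA_real_))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(expected >= 5)) {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    list(table = tab, method = "chisq",
         statistic = unname(ct$statistic), p = ct$p.value)
  } else {
    ft <- fisher.test(tab, workspace = 2e7)
    list(table = tab, method = "fisher", statistic = NA_real_,
         p = ft$p.value)
  }
}

#' Scanpath-similarity clustering across a cohort
#'
#' Splits cleaned trials by text-font pair, computes the normalized Scasim
#' matrix, embeds and clusters each, and tests cluster-group association.
#'
#' @param trials list of *cleaned* `trial_record`s.
#' @param config a [scasim_config()].
#' @param seed seed forwarded to [embed_and_cluster()].
#' @param min_trials smallest per-pair trial count analyzed.
#' @return data.frame, one row per text-font pair: `text`, `font`, `n`,
#'   `k`, `method`, `p`; attribute `details` holds the per-pair cluster
#'   results.
#' @export
similarity_analysis <- function(trials, config = scasim_config(), seed = 1L,
                                min_trials = 4) {
  key <- vapply(trials, function(tr) paste(tr$text_id, tr$font, sep = "_"), "")
  out <- list(); details <- list()
  for (k in unique(key)) {
    sub <- trials[key == k]
    if (length(sub) < min_trials) next
    M <- scasim_matrix(sub, config)
    cl <- embed_and_cluster(M, seed = seed)
    at <- association_test(cl$assignments, attr(M, "groups"))
    details[[k]] <- list(matrix = M, cluster = cl, association = at)
    out[[k]] <- data.frame(text = sub[[1]]$text_id, font = sub[[1]]$font,
                           n = length(sub), k = cl$k, method = at$method,
                           p = at$p)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "details") <- details
  res
}
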