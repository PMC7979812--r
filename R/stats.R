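#' Unbiased Hedges' g with exact noncentral-t confidence interval
#'
#' Computes the bias-corrected standardized mean difference
#' `g = J * (m1 - m2) / s_pooled` with `J = 1 - 3 / (4 * df - 1)`,
#' `df = n1 + n2 - 2`, and its exact analytical confidence interval obtained
#' by inverting the noncentral t distribution: the noncentrality parameters
#' whose distributions place the observed `t = d / sqrt(1/n1 + 1/n2)` at the
#' `(1-conf)/2` and `1-(1-conf)/2` quantiles are rescaled by
#' `sqrt(1/n1 + 1/n2)`. The CI is reported on the d scale (the convention of
#' the common effect-size toolboxes), which the point estimate's bias
#' correction does not rescale.
#'
#' Sample 1 is conventionally the control group, so that metrics on which
#' the dyslexia group is larger or longer carry a negative sign.
#'
#' @param m1,s1,n1 mean, SD and size of sample 1 (control).
#' @param m2,s2,n2 mean, SD and size of sample 2 (dyslexia).
#' @param conf confidence level.
#' @return an `effect_size` object: list with `g`, `ci` (lo, hi), `d`, `t`,
#'   `df`, `n1`, `n2`, `sign_convention`.
#' @export
hedges_g <- function(m1, s1, n1, m2, s2, n2, conf = 0.95) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group")
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df)
  if (sp <= 0) stop("zero pooled SD")
  d <- (m1 - m2) / sp
  J <- 1 - 3 / (4 * df - 1)
  se <- sqrt(1 / n1 + 1 / n2)
  tobs <- d / se
  alpha <- (1 - conf) / 2
  ncp_root <- function(p) {
    f <- function(l) suppressWarnings(pt(tobs, df, ncp = l)) - p
    span <- max(10, 3 * abs(tobs) + 10)
    uniroot(f, c(tobs - span, tobs + span), extendInt = "downX",
            tol = 1e-8)$root
  }
  lo <- ncp_root(1 - alpha) * se
  hi <- ncp_root(alpha) * se
  structure(list(g = J * d, ci = c(lo, hi), d = d, t = tobs, df = df,
                 n1 = n1, n2 = n2,
                 sign_convention = "negative = dyslexia larger/longer"),
            class = "effect_size")
}

#' @rdname hedges_g
#' @param x,y raw samples (x = control, y = dyslexia).
#' @export
hedges_g_samples <- function(x, y, conf = 0.95) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  hedges_g(mean(x), sd(x), length(x), mean(y), sd(y), length(y), conf)
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("Hedges' g = %.3f, %d%% CI [%.3f, %.3f] (n1 = %d, n2 = %d)\n",
              x$g, 95, x$ci[1], x$ci[2], x$n1, x$n2))
  cat("sign convention:", x$sign_convention, "\n")
  invisible(x)
}

#' Two-sided pooled-variance independent-samples t-test from summary stats
#'
#' @inheritParams hedges_g
#' @return list: `t`, `df`, `p`.
#' @export
independent_t <- function(m1, s1, n1, m2, s2, n2) {
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  if (sp2 <= 0) stop("zero pooled SD")
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' One-sample t-test of proportion scores against chance, Bonferroni-adjusted
#'
#' @param scores proportions in `[0, 1]`.
#' @param chance chance level (default 0.5).
#' @param n_tests Bonferroni family size (default 3).
#' @return list: `t`, `df`, `p_raw`, `p_adjusted`.
#' @export
one_sample_t_vs_chance <- function(scores, chance = 0.5, n_tests = 3) {
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  n <- length(scores)
  if (n < 2) stop("need n >= 2")
  s <- sd(scores)
  if (s == 0) {
    t <- if (mean(scores) == chance) 0 else Inf * sign(mean(scores) - chance)
    p <- if (is.infinite(t)) 0 else 1
  } else {
    t <- (mean(scores) - chance) / (s / sqrt(n))
    p <- 2 * pt(-abs(t), n - 1)
  }
  list(t = t, df = n - 1, p_raw = p, p_adjusted = min(1, p * n_tests))
}

#' JZS Bayes factor for a t statistic
#'
#' Jeffreys-Zellner-Siow BF10 with a Cauchy(0, `cauchy_width`) prior on the
#' standardized effect size, computed by numerical integration of the
#' noncentral-t marginal likelihood. One-sample when `n2` is `NULL`,
#' two-sample otherwise.
#'
#' @param t observed t statistic.
#' @param n1 sample size (group 1).
#' @param n2 optional group-2 size.
#' @param cauchy_width prior scale (default 0.7).
#' @return a `bayes_result`: list with `bf10`, `bf01`, `cauchy_width`.
#' @export
jzs_bf <- function(t, n1, n2 = NULL, cauchy_width = 0.7) {
  if (is.null(n2)) { neff <- n1; df <- n1 - 1 }
  else { neff <- n1 * n2 / (n1 + n2); df <- n1 + n2 - 2 }
  if (df < 1) stop("insufficient sample size")
  f <- function(delta)
    dcauchy(delta, 0, cauchy_width) *
      suppressWarnings(dt(t, df, ncp = delta * sqrt(neff)))
  m1 <- tryCatch(
    integrate(f, -Inf, Inf, rel.tol = 1e-9, abs.tol = 0)$value,
    error = function(e) stop("integration failed: ", conditionMessage(e)))
  m0 <- dt(t, df)
  structure(list(bf10 = m1 / m0, bf01 = m0 / m1,
                 cauchy_width = cauchy_width), class = "bayes_result")
}

#' Percentage-bend correlation
#'
#' Robust correlation that winsorizes a fixed fraction `beta` of extreme
#' standardized deviations in each variable: for each variable the
#' `(1-beta)` quantile omega of the absolute deviations from the median sets
#' the bend; standardized deviations are clipped to `[-1, 1]` via
#' `psi(u) = max(-1, min(1, u))` around the percentage-bend measure of
#' location, and the clipped scores are correlated. The p-value comes from
#' `t = r * sqrt((n-2) / (1-r^2))` on `n - 2` df.
#'
#' @param x,y equal-length numeric vectors, `n >= 4`.
#' @param beta bend fraction per direction (default 0.2).
#' @return list: `r`, `t`, `df`, `p`.
#' @export
percentage_bend_correlation <- function(x, y, beta = 0.2) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 4) stop("need n >= 4")
  bend_scores <- function(v) {
    m <- floor((1 - beta) * n + 0.5)
    omega <- sort(abs(v - median(v)))[m]
    if (omega <= 0) stop("bend scale omega is zero (over half the data at the median)")
    psi <- (v - median(v)) / omega
    i1 <- sum(psi < -1); i2 <- sum(psi > 1)
    loc <- (sum(v[psi >= -1 & psi <= 1]) + omega * (i2 - i1)) / (n - i1 - i2)
    pmin(1, pmax(-1, (v - loc) / omega))
  }
  a <- bend_scores(x); b <- bend_scores(y)
  r <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, t = tstat, df = n - 2, p = 2 * pt(-abs(tstat), n - 2))
}

#' Proportion of dyslexia-group readers consistent with the group effect
#'
#' Fraction of dyslexia participants whose trial-averaged metric lies on the
#' stated side of the control-group mean.
#'
#' @param participant_means_dys per-participant means, dyslexia group.
#' @param control_mean the control group's mean.
#' @param direction `"greater"` or `"less"`.
#' @return proportion in `[0, 1]`.
#' @export
proportion_consistent <- function(participant_means_dys, control_mean,
                                  direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (!length(participant_means_dys)) stop("need >= 1 participant mean")
  if (direction == "greater") mean(participant_means_dys > control_mean)
  else mean(participant_means_dys < control_mean)
}

#' Likelihood-ratio test from two model deviances
#'
#' @param deviance_full,deviance_reduced model deviances (reduced >= full
#'   expected; a negative difference warns and is clamped to 0 when
#'   `tolerant`).
#' @param df_diff difference in parameters (>= 1).
#' @param tolerant clamp negative statistics to zero instead of erroring.
#' @return list: `chisq`, `df`, `p`.
#' @export
lrt <- function(deviance_full, deviance_reduced, df_diff, tolerant = TRUE) {
  if (df_diff < 1) stop("df_diff must be >= 1")
  x2 <- deviance_reduced - deviance_full
  if (x2 < 0) {
    warning("reduced model fits better than full (negative X^2)")
    if (tolerant) x2 <- 0 else stop("negative likelihood-ratio statistic")
  }
  list(chisq = x2, df = df_diff, p = pchisq(x2, df_diff, lower.tail = FALSE))
}
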