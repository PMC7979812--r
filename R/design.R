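#' Build the reading-duration GLMM design
#'
#' Constructs the single-trial design for a gamma-family mixed model of
#' reading duration: mean-centred deviation codes for group, font and their
#' interaction (each column sums to ~0 by construction, exactly +/- 1/2 under
#' balance), plus the maximal no-correlation random-effects structure
#' (by-participant intercept and font slope; by-text intercept and group,
#' font and interaction slopes). Fitting is delegated to a mixed-model
#' backend (see [fit_reading_glmm()]); this function owns the design and the
#' collinearity check.
#'
#' @param trials data.frame with columns `group`, `font`, `participant`,
#'   `text`, `reading_duration` (positive).
#' @return a `design_spec`: list with `data` (input plus `group_c`, `font_c`,
#'   `gxf_c`), `formula_full`, `formula_reduced` (named list dropping each
#'   fixed effect), `family`, and `collinearity` (max absolute pairwise
#'   correlation among the coded predictors, with a `duplicated` flag).
#' @export
build_design <- function(trials) {
  need <- c("group", "font", "participant", "text", "reading_duration")
  if (!all(need %in% names(trials)))
    stop("missing column(s): ", paste(setdiff(need, names(trials)),
                                      collapse = ", "))
  if (any(trials$reading_duration <= 0))
    stop("reading_duration must be positive (gamma family)")
  for (v in c("group", "font"))
    if (length(unique(trials[[v]])) < 2)
      stop("single-level predictor: ", v)
  g <- as.numeric(factor(trials$group)) - 1   # second level = 1
  f <- as.numeric(factor(trials$font)) - 1
  d <- trials
  d$group_c <- g - mean(g)
  d$font_c <- f - mean(f)
  d$gxf_c <- d$group_c * d$font_c
  d$gxf_c <- d$gxf_c - mean(d$gxf_c)
  X <- cbind(group_c = d$group_c, font_c = d$font_c, gxf_c = d$gxf_c)
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    # a constant coded column (e.g. font perfectly confounded with group)
    offdiag <- 1
  } else {
    cc <- stats::cor(X)
    offdiag <- abs(cc[upper.tri(cc)])
  }
  rand <- paste("(1 | participant) + (0 + font_c | participant) +",
                "(1 | text) + (0 + group_c | text) +",
                "(0 + font_c | text) + (0 + gxf_c | text)")
  full <- paste("reading_duration ~ group_c + font_c + gxf_c +", rand)
  reduced <- list(
    group = paste("reading_duration ~ font_c + gxf_c +", rand),
    font = paste("reading_duration ~ group_c + gxf_c +", rand),
    interaction = paste("reading_duration ~ group_c + font_c +", rand))
  structure(list(data = d, formula_full = full, formula_reduced = reduced,
                 family = "Gamma(identity)",
                 collinearity = list(max_abs_cor = max(offdiag),
                                     duplicated = any(offdiag > 0.999))),
            class = "design_spec")
}

#' Fit the reading-duration GLMM (backend adapter)
#'
#' Thin adapter around `lme4::glmer` for a [build_design()] specification.
#' The package's contribution is the design and the likelihood-ratio
#' comparison ([lrt()]); the solver is delegated entirely.
#'
#' @param design a `design_spec`.
#' @param which `"full"` or one of the reduced models.
#' @param ... passed to `lme4::glmer`.
#' @return a fitted `glmerMod`.
#' @export
fit_reading_glmm <- function(design, which = "full", ...) {
  if (!requireNamespace("lme4", quietly = TRUE))
    stop("fit_reading_glmm requires the lme4 package")
  fo <- if (which == "full") design$formula_full else
    design$formula_reduced[[which]]
  if (is.null(fo)) stop("unknown model: ", which)
  lme4::glmer(stats::as.formula(fo), data = design$data,
              family = stats::Gamma(link = "identity"),
              control = lme4::glmerControl(optimizer = "bobyqa"), ...)
}
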