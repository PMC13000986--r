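## Publication-bias battery: cumulative meta-analysis by publication year,
## funnel-plot coordinates, and two Egger-type asymmetry regressions.

#' Cumulative meta-analysis by publication year
#'
#' Sorts effects ascending by publication year (ties broken by study then
#' record id) and refits the model on each year-closing prefix, giving the
#' evolution of the pooled estimate as the literature accumulated. The final
#' step is, by construction, the full-data fit.
#'
#' Prefixes too small to identify both nested variance components are still
#' fitted — the REML boundary check fixes the unidentified component at zero —
#' and flagged in the output.
#'
#' @param es Effect-size table (from [compute_effect_sizes()]) with `value`,
#'   `variance`, `publication_year`, `study_id`, `treatment_id`, `record_id`.
#' @param moderator,random,phylo Passed to [fit_multilevel()]; default is the
#'   intercept-only three-level model.
#' @return Data frame of class `seqherb_cumulative` with one row per distinct
#'   year: `year`, `k`, `estimate`, `ci_low`, `ci_high`, `sigma2_study`,
#'   `sigma2_treatment`, `boundary` (TRUE when a variance component was
#'   estimated as exactly zero).
#' @export
cumulative_meta <- function(es, moderator = NULL,
                            random = c(study = "study_id",
                                       treatment = "treatment_id"),
                            phylo = NULL) {
  es <- as.data.frame(es)
  if (anyNA(es$publication_year))
    stop("all records must carry a publication year")
  ord <- order(es$publication_year, es$study_id, es$record_id)
  es <- es[ord, , drop = FALSE]
  years <- sort(unique(es$publication_year))
  steps <- lapply(years, function(yr) {
    pre <- es[es$publication_year <= yr, , drop = FALSE]
    fit <- fit_multilevel(pre$value, pre$variance, data = pre,
                          moderator = moderator, random = random,
                          phylo = phylo)
    data.frame(year = yr, k = nrow(pre),
               estimate = unname(fit$beta[1]),
               ci_low = unname(fit$ci_low[1]),
               ci_high = unname(fit$ci_high[1]),
               sigma2_study = unname(fit$vc["sigma2_study"] %||% NA_real_),
               sigma2_treatment =
                 unname(fit$vc["sigma2_treatment"] %||% NA_real_),
               boundary = any(fit$vc == 0))
  })
  out <- do.call(rbind, steps)
  rownames(out) <- NULL
  class(out) <- c("seqherb_cumulative", "data.frame")
  out
}

#' Funnel-plot coordinates
#'
#' Plot-ready table of effect size against standard error, plus the pseudo
#' confidence rails `estimate +/- z * se` over the observed SE range (the
#' rails meet at the pooled estimate at `se = 0`).
#'
#' @param value,variance Effect sizes and their sampling variances.
#' @param estimate Pooled estimate for the rails; by default the three-level
#'   intercept-only fit cannot be computed without grouping information, so
#'   the inverse-variance weighted mean is used.
#' @param level Rail level (default 0.95).
#' @param n_rail Number of rail points.
#' @return List with `points` (value, se), `rails` (se, low, high) and
#'   `estimate`.
#' @export
funnel_coordinates <- function(value, variance, estimate = NULL,
                               level = 0.95, n_rail = 50L) {
  if (any(variance <= 0)) stop("variances must be positive")
  se <- sqrt(variance)
  if (is.null(estimate)) estimate <- sum(value / variance) / sum(1 / variance)
  z <- .CI_Z(level)
  rail_se <- seq(0, max(se), length.out = n_rail)
  list(points = data.frame(value = value, se = se),
       rails = data.frame(se = rail_se,
                          low = estimate - z * rail_se,
                          high = estimate + z * rail_se),
       estimate = estimate)
}

#' Egger-type regression test of funnel asymmetry
#'
#' Two variants are provided, matching the two ways asymmetry is commonly
#' tested in large multilevel syntheses:
#' \describe{
#'   \item{`"weighted_sei"`}{Random-effects metaregression of the effect on
#'     its standard error (the regression-test form applied per response
#'     category); the statistic is the Wald z of the SE coefficient. By
#'     default the model keeps the three-level random structure when the
#'     grouping columns are present, and falls back to a per-observation
#'     random effect otherwise.}
#'   \item{`"ols_inverse_variance"`}{Ordinary least squares of the effect on
#'     the inverse of its variance (the pooled-data form); the statistic is
#'     the slope F on (1, k-2) degrees of freedom.}
#' }
#'
#' @param value,variance Effect sizes and sampling variances (k >= 3).
#' @param variant `"weighted_sei"` or `"ols_inverse_variance"`.
#' @param data Optional data frame with grouping columns for the
#'   `weighted_sei` variant.
#' @param random Random structure for `weighted_sei`; defaults to the
#'   three-level structure when `data` has the columns, else `".row"`.
#' @return List of class `seqherb_egger`: `slope`, `slope_se`, `statistic`,
#'   `statistic_kind` ("z" or "F"), `df`, `p`, `variant`, `intercept`.
#' @export
egger_test <- function(value, variance,
                       variant = c("weighted_sei", "ols_inverse_variance"),
                       data = NULL, random = NULL) {
  variant <- match.arg(variant)
  k <- length(value)
  if (k < 3L) stop("Egger regression requires at least 3 effects")
  if (length(unique(variance)) == 1L)
    stop("constant predictor: all sampling variances identical")

  if (variant == "ols_inverse_variance") {
    fit <- lm(value ~ I(1 / variance))
    sm <- summary(fit)$coefficients
    slope <- sm[2, 1]; slope_se <- sm[2, 2]
    Fstat <- (slope / slope_se)^2
    res <- list(slope = slope, slope_se = slope_se, statistic = Fstat,
                statistic_kind = "F", df = c(1L, k - 2L),
                p = pf(Fstat, 1, k - 2, lower.tail = FALSE),
                variant = variant, intercept = sm[1, 1])
  } else {
    df_ <- if (is.null(data)) data.frame(sei = sqrt(variance))
           else cbind(as.data.frame(data), sei = sqrt(variance))
    if (is.null(random)) {
      random <- if (all(c("study_id", "treatment_id") %in% names(df_)))
        c(study = "study_id", treatment = "treatment_id")
      else c(unit = ".row")
    }
    fit <- fit_multilevel(value, variance, data = df_, moderator = ~sei,
                          random = random)
    slope <- unname(fit$beta["sei"]); slope_se <- unname(fit$se["sei"])
    zstat <- slope / slope_se
    res <- list(slope = slope, slope_se = slope_se, statistic = zstat,
                statistic_kind = "z", df = NA_integer_,
                p = 2 * pnorm(-abs(zstat)),
                variant = variant, intercept = unname(fit$beta["(Intercept)"]))
  }
  class(res) <- "seqherb_egger"
  res
}

#' @export
print.seqherb_egger <- function(x, ...) {
  cat("Egger-type asymmetry regression (", x$variant, ")\n", sep = "")
  cat("slope =", signif(x$slope, 4), "+/-", signif(x$slope_se, 4), "\n")
  if (x$statistic_kind == "F")
    cat("F(", x$df[1], ",", x$df[2], ") = ", signif(x$statistic, 4),
        ", p = ", signif(x$p, 3), "\n", sep = "")
  else
    cat("z = ", signif(x$statistic, 4), ", p = ", signif(x$p, 3), "\n",
        sep = "")
  invisible(x)
}
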