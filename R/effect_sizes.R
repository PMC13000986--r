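## Effect sizes from raw study summaries: Hedges' g for mean-based outcomes,
## log odds ratios for the binary (survival / choice) subset.

#' Pooled standard deviation of two arms
#'
#' \eqn{\sigma_p = \sqrt{\{(n_t-1)\sigma_t^2 + (n_c-1)\sigma_c^2\}/(n_t+n_c-2)}}
#'
#' @param sd_treatment,sd_control Nonnegative arm standard deviations.
#' @param n_treatment,n_control Positive arm sample sizes; the pooled
#'   denominator `n_t + n_c - 2` must be positive.
#' @return Pooled SD (vectorized).
#' @export
pooled_sd <- function(sd_treatment, sd_control, n_treatment, n_control) {
  if (any(n_treatment < 1 | n_control < 1, na.rm = TRUE))
    stop("sample sizes must be positive")
  if (any(n_treatment + n_control <= 2, na.rm = TRUE))
    stop("degenerate pooled-SD denominator: n_treatment + n_control must exceed 2")
  if (any(sd_treatment < 0 | sd_control < 0, na.rm = TRUE))
    stop("standard deviations must be nonnegative")
  sqrt(((n_treatment - 1) * sd_treatment^2 + (n_control - 1) * sd_control^2) /
         (n_treatment + n_control - 2))
}

#' Hedges' g standardized mean difference
#'
#' Computes the small-sample corrected standardized mean difference
#' \eqn{g = J\,(\bar{x}_t - \bar{x}_c)/\sigma_p} with
#' \eqn{J = 1 - 3/\{4(n_t+n_c-2) - 1\}} and the standard large-sample
#' sampling variance
#' \eqn{(n_t+n_c)/(n_t n_c) + g^2/\{2(n_t+n_c)\}}.
#'
#' @param mean_treatment,mean_control Arm means (outcome units).
#' @param sd_treatment,sd_control Arm standard deviations; the pooled SD must
#'   be strictly positive.
#' @param n_treatment,n_control Positive arm sample sizes.
#' @return A data frame with columns `value`, `variance`, `J`, `metric`
#'   (`"hedges_g"`), `sign_reversed` (`FALSE`; see
#'   [apply_sign_convention()]).
#' @examples
#' hedges_g(8, 10, 2, 2, 10, 10)
#' @export
hedges_g <- function(mean_treatment, mean_control, sd_treatment, sd_control,
                     n_treatment, n_control) {
  sp <- pooled_sd(sd_treatment, sd_control, n_treatment, n_control)
  if (any(sp == 0, na.rm = TRUE))
    stop("zero pooled standard deviation: effect size undefined (zero spread)")
  m <- n_treatment + n_control
  J <- 1 - 3 / (4 * (m - 2) - 1)
  g <- J * (mean_treatment - mean_control) / sp
  vg <- m / (n_treatment * n_control) + g^2 / (2 * m)
  data.frame(value = g, variance = vg, J = J,
             metric = "hedges_g", sign_reversed = FALSE,
             stringsAsFactors = FALSE)
}

#' Outcome-specific sign convention
#'
#' For outcomes where a larger raw value means *worse* performance
#' (development time of the herbivore; area of plant damage) the sign of the
#' effect is reversed once so that, throughout the pipeline, negative values
#' mean lower herbivore/plant performance after induction (induced
#' resistance) and positive values mean induced susceptibility.
#'
#' @param effect A one-or-more-row effect-size frame as returned by
#'   [hedges_g()] or [log_odds_ratio()], with a `sign_reversed` column.
#' @param outcome Outcome label(s), recycled to the rows of `effect`.
#' @return `effect` with `value` negated and `sign_reversed = TRUE` on rows
#'   whose outcome is `development_time` or `damage`.
#' @export
apply_sign_convention <- function(effect, outcome) {
  flip_outcomes <- c("development_time", "damage")
  outcome <- rep_len(outcome, nrow(effect))
  flip <- outcome %in% flip_outcomes
  if (any(effect$sign_reversed & flip))
    stop("sign convention already applied to one or more effects")
  effect$value[flip] <- -effect$value[flip]
  effect$sign_reversed[flip] <- TRUE
  effect
}

#' Log odds ratio from binary counts
#'
#' For records reporting individual survival or choice counts rather than a
#' mean and SD, the effect is the log odds ratio of the treatment arm against
#' the control arm,
#' \eqn{LOR = \log\{(a/b)/(c/d)\}} with
#' \eqn{a} = events in treatment, \eqn{b = n_t - a}, \eqn{c} = events in
#' control, \eqn{d = n_c - c}, and sampling variance
#' \eqn{1/a + 1/b + 1/c + 1/d}. When any cell of a table is zero, 0.5 is
#' added to all four cells of that table only.
#'
#' @param events_treatment,events_control Event counts (survivors, or
#'   individuals choosing the induced plant), `0 <= events <= n`.
#' @param n_treatment,n_control Positive arm sizes.
#' @return A data frame with `value`, `variance`, `J` (`NA`), `metric`
#'   (`"log_odds_ratio"`), `sign_reversed`.
#' @examples
#' log_odds_ratio(8, 4, 10, 10)
#' @export
log_odds_ratio <- function(events_treatment, events_control,
                           n_treatment, n_control) {
  if (any(n_treatment < 1 | n_control < 1))
    stop("sample sizes must be positive")
  if (any(events_treatment < 0 | events_control < 0 |
          events_treatment > n_treatment | events_control > n_control))
    stop("event counts must lie in [0, n] for each arm")
  both_none <- events_treatment == 0 & events_control == 0
  both_all  <- events_treatment == n_treatment & events_control == n_control
  if (any(both_none | both_all))
    stop("undefined odds: both arms all-events or all-nonevents")
  a <- events_treatment; b <- n_treatment - events_treatment
  c_ <- events_control;  d <- n_control - events_control
  zero <- a == 0 | b == 0 | c_ == 0 | d == 0
  a[zero] <- a[zero] + 0.5; b[zero] <- b[zero] + 0.5
  c_[zero] <- c_[zero] + 0.5; d[zero] <- d[zero] + 0.5
  lor <- log((a / b) / (c_ / d))
  vl <- 1 / a + 1 / b + 1 / c_ + 1 / d
  data.frame(value = lor, variance = vl, J = NA_real_,
             metric = "log_odds_ratio", sign_reversed = FALSE,
             stringsAsFactors = FALSE)
}

#' Compute effect sizes for every record of a dataset
#'
#' Mean-based records (means and SDs present) yield Hedges' g with the sign
#' convention of [apply_sign_convention()]; records carrying binary event
#' counts but no means yield log odds ratios. Records lacking the summaries
#' required for their metric (e.g. a mean-based outcome with a missing SD or
#' zero pooled SD) are excluded with a warning naming them — no imputation is
#' attempted.
#'
#' @param dataset A `seqherb_dataset` (or data frame in the canonical schema).
#' @return The dataset columns with `value`, `variance`, `metric`, `J` and
#'   `sign_reversed` appended; excluded records are dropped and listed in the
#'   `exclusions` attribute.
#' @export
compute_effect_sizes <- function(dataset) {
  d <- as.data.frame(dataset)
  has_mean <- !is.na(d$mean_treatment) & !is.na(d$mean_control) &
              !is.na(d$sd_treatment) & !is.na(d$sd_control)
  has_events <- !is.na(d$events_treatment) & !is.na(d$events_control)
  use_lor <- has_events & !has_mean
  use_g <- has_mean

  es <- data.frame(value = rep(NA_real_, nrow(d)), variance = NA_real_,
                   J = NA_real_, metric = NA_character_,
                   sign_reversed = FALSE, stringsAsFactors = FALSE)
  excluded <- character(0)

  if (any(use_g)) {
    i <- which(use_g)
    sp <- tryCatch(pooled_sd(d$sd_treatment[i], d$sd_control[i],
                             d$n_treatment[i], d$n_control[i]),
                   error = function(e) stop(e))
    bad <- sp == 0
    if (any(bad)) {
      excluded <- c(excluded, d$record_id[i[bad]])
      i <- i[!bad]
    }
    if (length(i)) {
      g <- hedges_g(d$mean_treatment[i], d$mean_control[i],
                    d$sd_treatment[i], d$sd_control[i],
                    d$n_treatment[i], d$n_control[i])
      g <- apply_sign_convention(g, d$outcome[i])
      es[i, names(g)] <- g
    }
  }
  if (any(use_lor)) {
    i <- which(use_lor)
    both_none <- d$events_treatment[i] == 0 & d$events_control[i] == 0
    both_all <- d$events_treatment[i] == d$n_treatment[i] &
                d$events_control[i]  == d$n_control[i]
    bad <- both_none | both_all
    if (any(bad)) {
      excluded <- c(excluded, d$record_id[i[bad]])
      i <- i[!bad]
    }
    if (length(i)) {
      l <- log_odds_ratio(d$events_treatment[i], d$events_control[i],
                          d$n_treatment[i], d$n_control[i])
      es[i, names(l)] <- l
    }
  }

  none <- !use_g & !use_lor
  excluded <- c(excluded, d$record_id[none])
  if (length(excluded))
    warning(length(excluded),
            " record(s) excluded from effect-size computation ",
            "(missing or degenerate summaries): ",
            paste(head(excluded, 10L), collapse = ", "),
            if (length(excluded) > 10L) " ..." else "")

  keep <- !is.na(es$value)
  out <- cbind(d[keep, , drop = FALSE], es[keep, , drop = FALSE])
  rownames(out) <- NULL
  attr(out, "exclusions") <- excluded
  attr(out, "provenance") <- attr(dataset, "provenance")
  out
}

#' Derived moderator columns used by the analysis plan
#'
#' Adds the ordered pair moderators (inducer trait followed by
#' subsequent-herbivore trait) and the plant life-history combination used in
#' the moderator analyses: `guild_pair`, `diet_pair`, `location_pair`,
#' `life_history` (life cycle x growth form). Guild strings are normalized to
#' lower case.
#'
#' @param es An effect-size table or dataset.
#' @return `es` with the derived columns appended.
#' @export
add_derived_moderators <- function(es) {
  pair <- function(a, b) ifelse(is.na(a) | is.na(b), NA_character_,
                                paste(tolower(trimws(a)), tolower(trimws(b)),
                                      sep = "->"))
  es$guild_pair <- pair(es$inducer_guild, es$subsequent_guild)
  es$diet_pair <- pair(es$inducer_diet, es$subsequent_diet)
  es$location_pair <- pair(es$inducer_location, es$subsequent_location)
  es$life_history <- ifelse(
    is.na(es$plant_life_cycle) | is.na(es$plant_growth_form), NA_character_,
    paste(es$plant_life_cycle, es$plant_growth_form, sep = "_"))
  es
}
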