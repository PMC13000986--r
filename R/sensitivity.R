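## Sensitivity analyses: representation of species, leave-one-species-out
## refits, and the binary-outcome (log odds ratio) validation subset.

.role_column <- function(role) {
  switch(match.arg(role, c("plant", "inducer", "subsequent")),
         plant = "plant_species",
         inducer = "inducer_species",
         subsequent = "subsequent_species")
}

#' Rank species by their share of observations
#'
#' For a given role (host plant, inducing herbivore, subsequent herbivore)
#' returns species ordered by the percentage of effect sizes they account
#' for; shares sum to 100 per role. Used to pick the most-studied species for
#' exclusion refits.
#'
#' @param data Dataset or effect-size table.
#' @param role `"plant"`, `"inducer"` or `"subsequent"`.
#' @return Data frame `species`, `n`, `share` (percent), descending by share.
#' @export
rank_species_by_representation <- function(data, role) {
  col <- .role_column(role)
  sp <- as.data.frame(data)[[col]]
  sp <- sp[!is.na(sp)]
  if (!length(sp)) stop("no species recorded for role: ", role)
  tab <- sort(table(sp), decreasing = TRUE)
  out <- data.frame(species = names(tab), n = as.integer(tab),
                    share = 100 * as.numeric(tab) / sum(tab),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Leave-one-species-out refit
#'
#' Refits the model on the dataset with every record involving the given
#' species (in the given role) removed, and reports the share of observations
#' removed, the estimate shift against the full fit, and whether the refit
#' confidence interval excludes the full-fit estimate — the criterion used to
#' call an exclusion consequential.
#'
#' @param es Effect-size table.
#' @param species Latin binomial to exclude (exact match after trimming).
#' @param role `"plant"`, `"inducer"` or `"subsequent"`.
#' @param moderator,random,phylo Passed to [fit_multilevel()].
#' @return List of class `seqherb_exclusion`: `excluded_species`, `role`,
#'   `share_of_observations`, `fit`, `full_fit`, `delta_vs_full`,
#'   `ci_excludes_full`.
#' @export
leave_species_out <- function(es, species, role,
                              moderator = NULL,
                              random = c(study = "study_id",
                                         treatment = "treatment_id"),
                              phylo = NULL) {
  col <- .role_column(role)
  es <- as.data.frame(es)
  drop <- !is.na(es[[col]]) & trimws(es[[col]]) == trimws(species)
  keep <- es[!drop, , drop = FALSE]
  if (!nrow(keep)) stop("excluding ", species, " empties the dataset")

  refit_on <- function(d) {
    if (!is.null(moderator)) {
      vars <- all.vars(as.formula(moderator))
      lost <- vapply(vars, function(vn) {
        full_lv <- unique(es[[vn]][!is.na(es[[vn]])])
        sub_lv <- unique(d[[vn]][!is.na(d[[vn]])])
        length(setdiff(full_lv, sub_lv)) > 0
      }, logical(1))
      if (any(lost)) {
        vn <- names(lost)[lost][1]
        gone <- setdiff(unique(es[[vn]]), unique(d[[vn]]))
        stop("exclusion empties moderator level(s) of '", vn, "': ",
             paste(gone, collapse = ", "))
      }
    }
    fit_multilevel(d$value, d$variance, data = d, moderator = moderator,
                   random = random, phylo = phylo)
  }
  full <- refit_on(es)
  fit <- refit_on(keep)
  b_full <- unname(full$beta[1]); b_sub <- unname(fit$beta[1])
  structure(list(
    excluded_species = species, role = role,
    share_of_observations = 100 * sum(drop) / nrow(es),
    fit = fit, full_fit = full,
    delta_vs_full = b_sub - b_full,
    ci_excludes_full = b_full < fit$ci_low[1] || b_full > fit$ci_high[1]),
    class = "seqherb_exclusion")
}

#' @export
print.seqherb_exclusion <- function(x, ...) {
  cat("Leave-one-species-out refit: ", x$excluded_species,
      " (", x$role, ", ", round(x$share_of_observations, 1),
      "% of observations removed)\n", sep = "")
  cat("estimate ", round(unname(x$fit$beta[1]), 4),
      " (full: ", round(unname(x$full_fit$beta[1]), 4),
      "; shift ", round(x$delta_vs_full, 4), ")\n", sep = "")
  cat(if (x$ci_excludes_full)
        "refit CI EXCLUDES the full-data estimate\n"
      else "refit CI contains the full-data estimate\n")
  invisible(x)
}

#' Binary-outcome validation analysis (log odds ratios)
#'
#' Runs the validation arm of the pipeline on the subset of records that
#' report individual survival or choice counts: computes log odds ratios,
#' fits the same three-level model per outcome class (survival;
#' feeding/oviposition choice), and tests the class contrast with an omnibus
#' QM.
#'
#' @param dataset A `seqherb_dataset` containing records with
#'   `events_treatment`/`events_control`.
#' @param random Random structure for the fits.
#' @return List of class `seqherb_lor_validation`: `fits` (named list of
#'   per-class intercept-only fits), `class_test` (QM of the class moderator
#'   across survival vs choice, when both present), `k`, `es` (the LOR
#'   table).
#' @export
lor_validation <- function(dataset,
                           random = c(study = "study_id",
                                      treatment = "treatment_id")) {
  d <- as.data.frame(dataset)
  sub <- d[!is.na(d$events_treatment) & !is.na(d$events_control), ,
           drop = FALSE]
  if (!nrow(sub)) stop("no records with binary event counts in the dataset")
  ## force the LOR path even if means were also reported
  sub$mean_treatment <- NA_real_; sub$mean_control <- NA_real_
  es <- suppressWarnings(compute_effect_sizes(sub))
  es$outcome_class <- ifelse(es$outcome == "survival", "survival", "choice")

  fits <- lapply(split(es, es$outcome_class), function(g) {
    fit_multilevel(g$value, g$variance, data = g, random = random)
  })

  class_test <- NULL
  if (length(unique(es$outcome_class)) > 1L) {
    cf <- fit_multilevel(es$value, es$variance, data = es,
                         moderator = ~outcome_class, random = random)
    class_test <- list(qm = cf$qm, qm_df = cf$qm_df, qm_p = cf$qm_p,
                       fit = cf)
  }
  structure(list(fits = fits, class_test = class_test, k = nrow(es), es = es),
            class = "seqherb_lor_validation")
}

#' @export
print.seqherb_lor_validation <- function(x, ...) {
  cat("Binary-outcome (LOR) validation, k =", x$k, "\n")
  for (nm in names(x$fits)) {
    f <- x$fits[[nm]]
    cat(sprintf("  %-10s LOR = %6.3f  [%6.3f, %6.3f]  k = %d  I^2 = %.1f%%\n",
                nm, f$beta[1], f$ci_low[1], f$ci_high[1], f$k,
                ifelse(is.na(f$i2), NA, f$i2)))
  }
  if (!is.null(x$class_test))
    cat("class contrast: QM =", round(x$class_test$qm, 3),
        "df =", x$class_test$qm_df,
        "p =", signif(x$class_test$qm_p, 3), "\n")
  invisible(x)
}
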