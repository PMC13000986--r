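## Full reproduction of the analysis plan: per-category overall models, every
## moderator analysis, the publication-bias battery and the sensitivity
## suite, emitted as plot-ready tables.

.CATS <- c("herbivore_performance", "herbivore_preference",
           "plant_performance")

#' Default analysis plan
#'
#' Ordered list of model specifications mirroring the published analysis:
#' per-category overall (intercept-only) models; outcome-type moderators
#' within each category; herbivore-trait moderators (ordered guild pair,
#' diet-breadth pair, feeding-location pair, conspecific inducer); plant
#' traits (life history, cultivation status); and experimental design
#' (setting, inducer removal, both feeding durations as linear terms in
#' days). Plant-performance moderator entries are additionally split into
#' biomass and damage subsets, matching how those responses are reported
#' separately.
#'
#' @return Data frame of class `seqherb_plan` with columns `label`
#'   (unique), `category`, `outcome_subset`, `moderator`, `anchor`.
#' @export
default_analysis_plan <- function() {
  entry <- function(label, category, moderator = NA_character_,
                    outcome_subset = NA_character_, anchor = "") {
    data.frame(label = label, category = category,
               outcome_subset = outcome_subset, moderator = moderator,
               anchor = anchor, stringsAsFactors = FALSE)
  }
  plan <- rbind(
    entry("overall_herbivore_performance", "herbivore_performance",
          anchor = "overall models"),
    entry("overall_herbivore_preference", "herbivore_preference",
          anchor = "overall models"),
    entry("overall_plant_performance", "plant_performance",
          anchor = "overall models"),
    entry("outcome_herbivore_performance", "herbivore_performance",
          "~outcome", anchor = "outcome moderators"),
    entry("outcome_herbivore_preference", "herbivore_preference",
          "~outcome", anchor = "outcome moderators"),
    entry("outcome_plant_performance", "plant_performance",
          "~outcome", anchor = "outcome moderators"))
  for (mod in c("guild_pair", "diet_pair", "location_pair", "same_species",
                "life_history", "plant_status", "setting", "inducer_removed",
                "duration_first", "duration_second")) {
    for (cat in .CATS) {
      if (cat == "plant_performance") {
        plan <- rbind(plan,
          entry(paste0(mod, "_plant_biomass"), cat, paste0("~", mod),
                "biomass", anchor = mod),
          entry(paste0(mod, "_plant_damage"), cat, paste0("~", mod),
                "damage", anchor = mod))
      } else {
        plan <- rbind(plan,
          entry(paste0(mod, "_", cat), cat, paste0("~", mod), anchor = mod))
      }
    }
  }
  stopifnot(!anyDuplicated(plan$label))
  class(plan) <- c("seqherb_plan", "data.frame")
  plan
}

.fit_plan_entry <- function(es, entry,
                            random = c(study = "study_id",
                                       treatment = "treatment_id"),
                            phylo = NULL) {
  sub <- es[es$response_category == entry$category &
              es$metric == "hedges_g", , drop = FALSE]
  if (!is.na(entry$outcome_subset))
    sub <- sub[sub$outcome == entry$outcome_subset, , drop = FALSE]
  moderator <- if (is.na(entry$moderator)) NULL else entry$moderator
  if (!is.null(moderator)) {
    vars <- all.vars(as.formula(moderator))
    sub <- sub[complete.cases(sub[, vars, drop = FALSE]), , drop = FALSE]
    ## a moderator with a single observed level reduces to the overall model
    single <- vapply(vars, function(vn)
      length(unique(sub[[vn]])) < 2L, logical(1))
    if (any(single)) moderator <- NULL
  }
  if (nrow(sub) < 2L) stop("fewer than 2 usable effects for ", entry$label)
  fit <- fit_multilevel(sub$value, sub$variance, data = sub,
                        moderator = moderator, random = random,
                        phylo = phylo)
  list(fit = fit, k = nrow(sub), data = sub)
}

.fit_table <- function(label, fit, k) {
  data.frame(label = label, term = names(fit$beta),
             estimate = unname(fit$beta), se = unname(fit$se),
             ci_low = unname(fit$ci_low), ci_high = unname(fit$ci_high),
             k = k, sigma2_study = unname(fit$vc["sigma2_study"] %||% NA_real_),
             sigma2_treatment =
               unname(fit$vc["sigma2_treatment"] %||% NA_real_),
             i2 = fit$i2, qm = fit$qm, qm_df = fit$qm_df, qm_p = fit$qm_p,
             pi_low = fit$pi_low, pi_high = fit$pi_high,
             converged = fit$converged, stringsAsFactors = FALSE)
}

#' Run the full reproduction pipeline
#'
#' Computes effect sizes, fits every entry of the analysis plan, runs the
#' publication-bias battery (cumulative meta-analysis by year, funnel
#' coordinates, both Egger variants) and the sensitivity suite
#' (leave-one-species-out for the three most-studied species per role, the
#' binary LOR validation, and optional phylogeny-augmented overall models),
#' writing one TSV per stage plus a JSON summary and a plain-text log.
#' Stage errors are recorded and remaining stages continue.
#'
#' @param dataset A validated `seqherb_dataset`.
#' @param plan Analysis plan (default [default_analysis_plan()]).
#' @param out_dir Output directory (created if needed); `NULL` to skip
#'   writing and just return the bundle.
#' @param bias,sensitivity Toggles for the respective batteries.
#' @param phylo Optional named list of `list(taxon=, corr=)` specifications;
#'   each is fitted as a separate phylogeny-augmented overall model (one
#'   phylogeny at a time).
#' @param n_exclude Most-studied species per role to leave out.
#' @return List of class `seqherb_report`: `models` (coefficient table over
#'   all plan entries), `fits`, `bias`, `sensitivity`, `errors`, `summary`.
#' @export
run_reproduction <- function(dataset, plan = default_analysis_plan(),
                             out_dir = NULL, bias = TRUE, sensitivity = TRUE,
                             phylo = NULL, n_exclude = 3L) {
  log_lines <- character(0)
  errors <- list()
  note <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ...)
    log_lines <<- c(log_lines, line)
  }
  safely <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      errors[[label]] <<- conditionMessage(e)
      note("ERROR ", label, ": ", conditionMessage(e))
      NULL
    })
  }

  note("reproduction started; records = ", nrow(dataset))
  es <- withCallingHandlers(
    add_derived_moderators(compute_effect_sizes(dataset)),
    warning = function(w) {
      note("WARN ", conditionMessage(w)); invokeRestart("muffleWarning")
    })
  note("effect sizes computed: ", nrow(es), " (",
       sum(es$metric == "hedges_g"), " Hedges' g, ",
       sum(es$metric == "log_odds_ratio"), " LOR)")

  fits <- list(); tables <- list()
  for (i in seq_len(nrow(plan))) {
    entry <- plan[i, ]
    res <- safely(entry$label, .fit_plan_entry(es, entry))
    if (is.null(res)) next
    fits[[entry$label]] <- res$fit
    tables[[entry$label]] <- .fit_table(entry$label, res$fit, res$k)
    note("fit ", entry$label, ": k = ", res$k,
         ", estimate = ", round(unname(res$fit$beta[1]), 4))
  }
  models <- do.call(rbind, tables)
  rownames(models) <- NULL

  bias_out <- NULL
  if (bias) {
    g_all <- es[es$metric == "hedges_g", , drop = FALSE]
    bias_out <- list(
      egger_pooled = safely("egger_pooled",
        egger_test(g_all$value, g_all$variance,
                   variant = "ols_inverse_variance")),
      egger_by_category = lapply(setNames(.CATS, .CATS), function(cat) {
        sub <- g_all[g_all$response_category == cat, , drop = FALSE]
        safely(paste0("egger_", cat),
               egger_test(sub$value, sub$variance, variant = "weighted_sei",
                          data = sub))
      }),
      cumulative = lapply(setNames(.CATS, .CATS), function(cat) {
        sub <- g_all[g_all$response_category == cat, , drop = FALSE]
        safely(paste0("cumulative_", cat), cumulative_meta(sub))
      }),
      funnel = lapply(setNames(.CATS, .CATS), function(cat) {
        sub <- g_all[g_all$response_category == cat, , drop = FALSE]
        est <- if (!is.null(fits[[paste0("overall_", cat)]]))
          unname(fits[[paste0("overall_", cat)]]$beta[1]) else NULL
        funnel_coordinates(sub$value, sub$variance, estimate = est)
      }))
    note("publication-bias battery complete")
  }

  sens_out <- NULL
  if (sensitivity) {
    g_all <- es[es$metric == "hedges_g", , drop = FALSE]
    exclusions <- list()
    for (role in c("plant", "inducer", "subsequent")) {
      ranked <- safely(paste0("rank_", role),
                       rank_species_by_representation(g_all, role))
      if (is.null(ranked)) next
      for (sp in head(ranked$species, n_exclude)) {
        lab <- paste0("exclude_", role, "_", gsub(" ", "_", sp))
        exclusions[[lab]] <- safely(lab, leave_species_out(g_all, sp, role))
      }
    }
    lor <- safely("lor_validation", lor_validation(dataset))
    phylo_fits <- NULL
    if (!is.null(phylo)) {
      phylo_fits <- lapply(setNames(names(phylo), names(phylo)),
        function(nm) {
          spec <- phylo[[nm]]
          safely(paste0("phylo_", nm), {
            keep <- g_all[[spec$taxon]] %in% rownames(spec$corr)
            sub <- g_all[keep, , drop = FALSE]
            lapply(setNames(.CATS, .CATS), function(cat) {
              d <- sub[sub$response_category == cat, , drop = FALSE]
              fit_multilevel(d$value, d$variance, data = d, phylo = spec)
            })
          })
        })
    }
    sens_out <- list(exclusions = exclusions, lor = lor,
                     phylo = phylo_fits)
    note("sensitivity suite complete")
  }

  summary <- list(
    n_records = nrow(dataset),
    n_effects = nrow(es),
    n_studies = length(unique(dataset$study_id)),
    k_by_category = as.list(table(
      es$response_category[es$metric == "hedges_g"])),
    overall = lapply(setNames(.CATS, .CATS), function(cat) {
      f <- fits[[paste0("overall_", cat)]]
      if (is.null(f)) return(NULL)
      list(estimate = unname(f$beta[1]), ci_low = unname(f$ci_low[1]),
           ci_high = unname(f$ci_high[1]), i2 = f$i2, k = f$k,
           pi_low = f$pi_low, pi_high = f$pi_high)
    }),
    errors = errors)
  note("reproduction finished; ", length(errors), " stage error(s)")

  report <- structure(list(models = models, fits = fits, bias = bias_out,
                           sensitivity = sens_out, errors = errors,
                           summary = summary, log = log_lines, es = es),
                      class = "seqherb_report")
  if (!is.null(out_dir)) .write_report(report, out_dir)
  report
}

.write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(d, f) utils::write.table(
    d, file.path(out_dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
  tsv(report$models, "model_estimates.tsv")
  if (!is.null(report$bias)) {
    for (nm in names(report$bias$cumulative)) {
      cm <- report$bias$cumulative[[nm]]
      if (!is.null(cm)) tsv(cm, paste0("cumulative_", nm, ".tsv"))
    }
    eg <- report$bias$egger_pooled
    if (!is.null(eg))
      tsv(data.frame(variant = eg$variant, slope = eg$slope,
                     slope_se = eg$slope_se, statistic = eg$statistic,
                     p = eg$p), "egger_pooled.tsv")
  }
  if (!is.null(report$sensitivity) && length(report$sensitivity$exclusions)) {
    ex <- report$sensitivity$exclusions
    keep <- !vapply(ex, is.null, logical(1))
    if (any(keep))
      tsv(do.call(rbind, lapply(ex[keep], function(e)
        data.frame(species = e$excluded_species, role = e$role,
                   share = e$share_of_observations,
                   estimate = unname(e$fit$beta[1]),
                   delta = e$delta_vs_full,
                   ci_excludes_full = e$ci_excludes_full))),
        "species_exclusions.tsv")
  }
  jsonlite::write_json(report$summary,
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  writeLines(report$log, file.path(out_dir, "reproduction.log"))
  invisible(out_dir)
}

#' @export
print.seqherb_report <- function(x, ...) {
  cat("<seqherb_report>", x$summary$n_effects, "effect sizes from",
      x$summary$n_studies, "studies\n")
  for (cat_ in names(x$summary$overall)) {
    o <- x$summary$overall[[cat_]]
    if (is.null(o)) next
    cat(sprintf("  %-22s g = %6.3f [%6.3f, %6.3f]  k = %d  I^2 = %.1f%%\n",
                cat_, o$estimate, o$ci_low, o$ci_high, o$k, o$i2))
  }
  if (length(x$errors))
    cat("stage errors:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}
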