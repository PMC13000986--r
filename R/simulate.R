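## Synthetic sequential-herbivory datasets with known generating truth.
## The generator emits RAW study summaries (arm means, SDs, sample sizes,
## binary counts), not effect sizes, so the whole pipeline — effect-size
## computation, sign conventions, multilevel fitting, bias and sensitivity
## analyses — is exercised end to end and can be checked against the
## configured truth.

## Deterministic per-study seed streams: a small multiplicative hash of the
## global seed and the study index feeds set.seed, so draws for one study
## never depend on how many other studies exist.
.mix_seed <- function(seed, ...) {
  h <- as.numeric(seed) %% 2147483647
  for (k in c(...)) h <- (h * 48271 + as.numeric(k) + 1) %% 2147483647
  as.integer(h)
}

## Species pools with representation weights emulating the skew of the
## extracted literature (a few heavily studied crop/pest systems dominate).
.plant_pool <- function() {
  top <- c("Brassica oleracea" = 0.135, "Brassica nigra" = 0.118,
           "Solanum lycopersicum" = 0.108)
  filler <- c("Arabidopsis thaliana", "Nicotiana attenuata", "Zea mays",
              "Brassica rapa", "Solanum dulcamara", "Plantago lanceolata",
              "Phaseolus lunatus", "Gossypium hirsutum", "Cucumis sativus",
              "Medicago truncatula", "Salix cinerea", "Betula pendula",
              "Quercus robur", "Pinus sylvestris", "Triticum aestivum",
              "Hordeum vulgare", "Vicia faba")
  w <- c(top, setNames(rep((1 - sum(top)) / length(filler), length(filler)),
                       filler))
  w / sum(w)
}

.herbivore_traits <- function() {
  ## species -> feeding guild, diet breadth, feeding location
  tr <- rbind(
    c("Brevicoryne brassicae",  "sap_feeder", "specialist", "aboveground"),
    c("Plutella xylostella",    "chewer",     "specialist", "aboveground"),
    c("Meloidogyne incognita",  "nematode",   "generalist", "belowground"),
    c("Tetranychus urticae",    "mite",       "generalist", "aboveground"),
    c("Myzus persicae",         "sap_feeder", "generalist", "aboveground"),
    c("Spodoptera exigua",      "chewer",     "generalist", "aboveground"),
    c("Spodoptera littoralis",  "chewer",     "generalist", "aboveground"),
    c("Pieris brassicae",       "chewer",     "specialist", "aboveground"),
    c("Pieris rapae",           "chewer",     "specialist", "aboveground"),
    c("Mamestra brassicae",     "chewer",     "generalist", "aboveground"),
    c("Trichoplusia ni",        "chewer",     "generalist", "aboveground"),
    c("Helicoverpa zea",        "chewer",     "generalist", "aboveground"),
    c("Manduca sexta",          "chewer",     "specialist", "aboveground"),
    c("Aphis fabae",            "sap_feeder", "generalist", "aboveground"),
    c("Macrosiphum euphorbiae", "sap_feeder", "generalist", "aboveground"),
    c("Bemisia tabaci",         "sap_feeder", "generalist", "aboveground"),
    c("Frankliniella occidentalis", "sap_feeder", "generalist", "aboveground"),
    c("Leptinotarsa decemlineata", "chewer",  "specialist", "aboveground"),
    c("Diabrotica virgifera",   "chewer",     "specialist", "belowground"),
    c("Pratylenchus penetrans", "nematode",   "generalist", "belowground"),
    c("Heterodera schachtii",   "nematode",   "specialist", "belowground"),
    c("Agriotes lineatus",      "chewer",     "generalist", "belowground"),
    c("Odocoileus virginianus", "mammal",     "generalist", "aboveground"),
    c("Microtus agrestis",      "mammal",     "generalist", "aboveground"))
  data.frame(species = tr[, 1], guild = tr[, 2], diet = tr[, 3],
             location = tr[, 4], stringsAsFactors = FALSE)
}

.herbivore_weights <- function(role) {
  tr <- .herbivore_traits()
  w <- setNames(rep(1, nrow(tr)), tr$species)
  mammals <- tr$species[tr$guild == "mammal"]
  if (role == "inducer") {
    w[c("Brevicoryne brassicae", "Plutella xylostella",
        "Meloidogyne incognita")] <- NA  # placeholders, set below
    rest <- setdiff(names(w), c("Brevicoryne brassicae", "Plutella xylostella",
                                "Meloidogyne incognita", mammals))
    w[rest] <- (1 - 0.059 - 0.055 - 0.054 - 0.01) / length(rest)
    w["Brevicoryne brassicae"] <- 0.059
    w["Plutella xylostella"] <- 0.055
    w["Meloidogyne incognita"] <- 0.054
    w[mammals] <- 0.01 / length(mammals)   # mammal inducers are rare
  } else {
    w[mammals] <- 0                        # no mammals as subsequent herbivore
    top <- c("Tetranychus urticae" = 0.074, "Myzus persicae" = 0.059,
             "Plutella xylostella" = 0.059)
    rest <- setdiff(names(w)[w > 0], names(top))
    w[rest] <- (1 - sum(top)) / length(rest)
    w[names(top)] <- top
  }
  w / sum(w)
}

#' Configuration of the synthetic-data generator
#'
#' Defaults emulate the shape of the extracted sequential-herbivory
#' literature: 161 studies contributing roughly 1500 effect sizes (1-4
#' treatments per study sharing a control, 1-7 records per treatment), the
#' three response categories in proportions 834:339:172 among mean-based
#' records, a binary-outcome subset of fraction 160/1505, publication years
#' 1985-2023, heavily skewed species representation, and true category means
#' equal to the pooled estimates of the synthesis the package reproduces
#' (herbivore performance -0.326, preference -0.142, plant performance
#' -0.013 on the g scale). Between-study and treatment-within-study variance
#' components default to 0.55 and 0.35, which at the default group sizes
#' (10-30 per arm) put the multilevel I-squared near 88%.
#'
#' @param n_studies Number of studies (publications).
#' @param treatments_per_study Integer range, treatments sharing a control.
#' @param records_per_treatment Integer range, records per treatment.
#' @param true_intercept True mean effect (g scale) of the reference
#'   category, herbivore performance.
#' @param moderator_effects Named shifts of the other response categories
#'   relative to the intercept.
#' @param sigma2_study,sigma2_treatment True variance components.
#' @param sigma2_taxon Optional taxon-level variance; requires `tree` (or one
#'   is simulated over the plant pool).
#' @param tree Optional `phylo` object for the taxon effect.
#' @param group_sizes Integer range of per-arm sample sizes.
#' @param sd_scale True within-arm standard deviation (outcome units).
#' @param binary_fraction Fraction of records reporting binary counts.
#' @param lor_targets True log odds ratios of the binary subset, by outcome.
#' @param control_props Control-arm event probabilities (survival, choice).
#' @param year_range Publication-year range.
#' @param seed Default seed used when [simulate_dataset()] is not given one.
#' @return A `seqherb_simconfig` list.
#' @export
simulation_config <- function(n_studies = 161,
                              treatments_per_study = c(1L, 4L),
                              records_per_treatment = c(1L, 7L),
                              true_intercept = -0.326,
                              moderator_effects = c(
                                herbivore_preference = 0.184,
                                plant_performance = 0.313),
                              sigma2_study = 0.55,
                              sigma2_treatment = 0.35,
                              sigma2_taxon = NULL,
                              tree = NULL,
                              group_sizes = c(10L, 30L),
                              sd_scale = 1,
                              binary_fraction = 160 / 1505,
                              lor_targets = c(survival = -0.80,
                                              feeding_choice = 0,
                                              oviposition_choice = -0.6),
                              control_props = c(survival = 0.7,
                                                choice = 0.5),
                              year_range = c(1985L, 2023L),
                              seed = 1L) {
  cfg <- list(n_studies = n_studies,
              treatments_per_study = as.integer(treatments_per_study),
              records_per_treatment = as.integer(records_per_treatment),
              true_intercept = true_intercept,
              moderator_effects = moderator_effects,
              sigma2_study = sigma2_study,
              sigma2_treatment = sigma2_treatment,
              sigma2_taxon = sigma2_taxon, tree = tree,
              group_sizes = as.integer(group_sizes),
              sd_scale = sd_scale,
              binary_fraction = binary_fraction,
              lor_targets = lor_targets,
              control_props = control_props,
              year_range = as.integer(year_range),
              seed = as.integer(seed))
  .validate_simconfig(cfg)
  structure(cfg, class = "seqherb_simconfig")
}

.validate_simconfig <- function(cfg) {
  stopifnot(cfg$n_studies >= 1,
            length(cfg$treatments_per_study) == 2,
            cfg$treatments_per_study[1] >= 1,
            diff(cfg$treatments_per_study) >= 0,
            length(cfg$records_per_treatment) == 2,
            cfg$records_per_treatment[1] >= 1,
            diff(cfg$records_per_treatment) >= 0,
            cfg$sigma2_study >= 0, cfg$sigma2_treatment >= 0,
            is.null(cfg$sigma2_taxon) || cfg$sigma2_taxon >= 0,
            cfg$group_sizes[1] >= 2, diff(cfg$group_sizes) >= 0,
            cfg$sd_scale > 0,
            cfg$binary_fraction >= 0, cfg$binary_fraction <= 1,
            all(cfg$control_props > 0), all(cfg$control_props < 1),
            diff(cfg$year_range) >= 0)
  bad <- plogis(qlogis(cfg$control_props["survival"]) +
                  cfg$lor_targets["survival"])
  if (bad <= 0 || bad >= 1)
    stop("infeasible config: binary proportion outside (0,1)")
  invisible(cfg)
}

#' Simulate an ultrametric pure-birth phylogeny over named taxa
#'
#' @param taxa At least two taxon names.
#' @param seed Integer seed; the tree is reproducible from `(taxa, seed)`.
#' @return An ultrametric `phylo` with the given tip labels.
#' @export
simulate_tree <- function(taxa, seed = 1L) {
  taxa <- unique(taxa)
  if (length(taxa) < 2L) stop("at least 2 taxa required")
  seed <- as.integer(seed)   # force before touching the global RNG state
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.mix_seed(seed, 7L, 7L, 7L))
  tree <- ape::rphylo(length(taxa), birth = 1, death = 0)
  tree$tip.label <- sample(taxa)     # detach label order from tree topology
  tree
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

.sample_range <- function(range, n = 1L) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Simulate a sequential-herbivory dataset with known truth
#'
#' For each record a true effect
#' \eqn{\theta = \mu + \delta_{category} + u_{study} + u_{treatment}
#' (+ u_{taxon})} is realized; mean-based records then draw raw two-arm
#' normal summaries (control mean 0, true SD `sd_scale`, treatment mean
#' \eqn{\theta \cdot} `sd_scale`; observed SDs from the scaled-chi sampling
#' distribution) so that the computed Hedges' g is centered on \eqn{\theta}
#' with its implied sampling variance. Records with sign-reversed outcomes
#' (development time, damage) draw the treatment mean at \eqn{-\theta} so
#' the convention applied downstream recovers \eqn{\theta}. Binary records
#' draw event counts from proportions consistent with the target log odds
#' ratios, sharing the same study/treatment deviates on the logit scale.
#'
#' Each study has its own deterministic random stream derived from
#' `(seed, study index)`, so enlarging `n_studies` leaves existing studies
#' unchanged.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return List with `dataset` (a validated `seqherb_dataset`) and `truth`
#'   (class `seqherb_simtruth`): realized study/treatment/taxon deviates,
#'   per-record true effects, the config and seed.
#' @export
simulate_dataset <- function(config = simulation_config(),
                             seed = config$seed) {
  .validate_simconfig(config)
  seed <- as.integer(seed)   # force before touching the global RNG state
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  plants <- .plant_pool()
  herb <- .herbivore_traits()
  w_ind <- .herbivore_weights("inducer")
  w_sub <- .herbivore_weights("subsequent")
  cat_probs <- c(herbivore_performance = 834, herbivore_preference = 339,
                 plant_performance = 172) / 1345

  ## taxon (plant) effects, correlated by the tree when requested
  u_taxon <- setNames(rep(0, length(plants)), names(plants))
  tree <- config$tree
  if (!is.null(config$sigma2_taxon) && config$sigma2_taxon > 0) {
    if (is.null(tree)) tree <- simulate_tree(names(plants), seed)
    R <- correlation_from_tree(tree)
    miss <- setdiff(names(plants), rownames(R))
    if (length(miss))
      stop("tree lacks taxa from the plant pool: ",
           paste(head(miss, 3L), collapse = ", "))
    R <- R[names(plants), names(plants)]
    set.seed(.mix_seed(seed, 0L))
    ev <- eigen((R + base::t(R)) / 2, symmetric = TRUE)
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(R))
    u_taxon <- setNames(
      sqrt(config$sigma2_taxon) * as.numeric(L %*% rnorm(nrow(R))),
      names(plants))
  }

  rows <- vector("list", config$n_studies)
  u_study_all <- numeric(config$n_studies)
  u_trt_all <- list()
  for (s in seq_len(config$n_studies)) {
    set.seed(.mix_seed(seed, s))
    study_id <- sprintf("S%03d", s)
    u_s <- rnorm(1, 0, sqrt(config$sigma2_study))
    u_study_all[s] <- u_s

    year <- .sample_range(config$year_range)
    setting <- if (runif(1) < 0.8) "glasshouse" else "field"
    plant <- sample(names(plants), 1, prob = plants)
    annual <- runif(1) < 0.7
    growth <- if (!annual && runif(1) < 0.6) "woody" else "herbaceous"
    status <- if (runif(1) < ifelse(annual, 0.75, 0.3)) "cultivated" else "wild"
    sub_sp <- sample(herb$species, 1, prob = w_sub[herb$species])
    sub_tr <- herb[herb$species == sub_sp, ]

    n_trt <- .sample_range(config$treatments_per_study)
    u_t_vec <- rnorm(n_trt, 0, sqrt(config$sigma2_treatment))
    u_trt_all[[s]] <- setNames(u_t_vec, sprintf("%s.T%d", study_id,
                                                seq_len(n_trt)))
    srows <- list()
    for (tix in seq_len(n_trt)) {
      treatment_id <- sprintf("%s.T%d", study_id, tix)
      ind_sp <- sample(herb$species, 1, prob = w_ind[herb$species])
      ind_tr <- herb[herb$species == ind_sp, ]
      dur1 <- round(exp(rnorm(1, log(7), 0.6)), 1)
      dur2 <- round(exp(rnorm(1, log(7), 0.6)), 1)
      removed <- runif(1) < 0.7
      n_rec <- .sample_range(config$records_per_treatment)
      for (r in seq_len(n_rec)) {
        binary <- runif(1) < config$binary_fraction
        if (binary) {
          outcome <- sample(c("survival", "feeding_choice",
                              "oviposition_choice"), 1,
                            prob = c(0.5, 0.25, 0.25))
          category <- if (outcome == "survival") "herbivore_performance"
                      else "herbivore_preference"
        } else {
          category <- sample(names(cat_probs), 1, prob = cat_probs)
          outcome <- switch(category,
            herbivore_performance = sample(
              c("growth", "survival", "fecundity", "development_time"), 1,
              prob = c(0.4, 0.2, 0.2, 0.2)),
            herbivore_preference = sample(
              c("feeding_choice", "oviposition_choice"), 1),
            plant_performance = sample(
              c("biomass", "damage", "reproduction"), 1,
              prob = c(0.5, 0.35, 0.15)))
        }
        u_t <- u_t_vec[tix]
        shift <- if (category %in% names(config$moderator_effects))
          config$moderator_effects[[category]] else 0
        theta <- config$true_intercept + shift + u_s + u_t + u_taxon[[plant]]

        nt <- .sample_range(config$group_sizes)
        nc <- .sample_range(config$group_sizes)
        rec <- list(
          record_id = sprintf("%s.R%d", treatment_id, r),
          study_id = study_id, treatment_id = treatment_id,
          response_category = category, outcome = outcome,
          mean_treatment = NA_real_, mean_control = NA_real_,
          sd_treatment = NA_real_, sd_control = NA_real_,
          n_treatment = nt, n_control = nc,
          events_treatment = NA_integer_, events_control = NA_integer_,
          publication_year = year, setting = setting,
          inducer_removed = removed,
          duration_first = dur1, duration_second = dur2,
          plant_species = plant, inducer_species = ind_sp,
          subsequent_species = sub_sp,
          plant_life_cycle = if (annual) "annual" else "perennial",
          plant_growth_form = growth, plant_status = status,
          inducer_guild = ind_tr$guild, subsequent_guild = sub_tr$guild,
          inducer_diet = ind_tr$diet, subsequent_diet = sub_tr$diet,
          inducer_location = ind_tr$location,
          subsequent_location = sub_tr$location,
          same_species = ind_sp == sub_sp,
          .theta = theta, .binary = binary)

        if (binary) {
          cls <- if (outcome == "survival") "survival" else "choice"
          p_c <- config$control_props[[cls]]
          lam <- config$lor_targets[[outcome]]
          p_t <- plogis(qlogis(p_c) + lam + u_s + u_t)
          for (try in 1:20) {   # avoid the undefined both-all/none tables
            et <- rbinom(1, nt, p_t); ec <- rbinom(1, nc, p_c)
            if (!((et == 0 && ec == 0) || (et == nt && ec == nc))) break
          }
          rec$events_treatment <- et; rec$events_control <- ec
          rec$.theta <- qlogis(p_t) - qlogis(p_c)  # true LOR for this record
        } else {
          sdt <- config$sd_scale
          flip <- outcome %in% c("development_time", "damage")
          mu_t <- (if (flip) -theta else theta) * sdt
          rec$mean_control <- rnorm(1, 0, sdt / sqrt(nc))
          rec$mean_treatment <- rnorm(1, mu_t, sdt / sqrt(nt))
          rec$sd_control <- sdt * sqrt(rchisq(1, nc - 1) / (nc - 1))
          rec$sd_treatment <- sdt * sqrt(rchisq(1, nt - 1) / (nt - 1))
        }
        srows[[length(srows) + 1L]] <- rec
      }
    }
    rows[[s]] <- srows
  }

  recs <- unlist(rows, recursive = FALSE)
  fields <- names(recs[[1]])
  flat <- as.data.frame(
    setNames(lapply(fields, function(f)
      unlist(lapply(recs, `[[`, f), use.names = FALSE)), fields),
    stringsAsFactors = FALSE)
  theta <- flat$.theta; binary <- flat$.binary
  flat$.theta <- NULL; flat$.binary <- NULL
  ds <- dataset_from_table(flat, provenance = list(
    source = sprintf("<simulated seed=%d>", seed), schema_version = "1.0"))

  truth <- structure(list(
    config = config, seed = as.integer(seed),
    u_study = setNames(u_study_all, sprintf("S%03d",
                                            seq_len(config$n_studies))),
    u_treatment = unlist(u_trt_all),
    u_taxon = u_taxon,
    theta = setNames(theta, flat$record_id),
    is_binary = setNames(binary, flat$record_id)),
    class = "seqherb_simtruth")
  list(dataset = ds, truth = truth)
}

#' Simulate plain funnel data for asymmetry diagnostics
#'
#' Generates `k` independent effects with heterogeneity `tau2` and variances
#' uniform on `v_range`; when `bias` is nonzero a small-study effect is
#' injected by inflating each effect by `bias * se`, the classic mechanism
#' Egger-type regressions are designed to detect.
#'
#' @param k Number of effects.
#' @param mu True mean effect.
#' @param tau2 Between-effect heterogeneity.
#' @param bias Small-study-effect coefficient (per unit SE).
#' @param v_range Range of sampling variances.
#' @param seed Integer seed.
#' @return Data frame `record_id`, `study_id`, `treatment_id`, `value`,
#'   `variance` (one study per effect).
#' @export
simulate_funnel_effects <- function(k, mu = 0, tau2 = 0.1, bias = 0,
                                    v_range = c(0.02, 0.3), seed = 1L) {
  seed <- as.integer(seed)   # force before touching the global RNG state
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.mix_seed(seed, 99L))
  v <- runif(k, v_range[1], v_range[2])
  y <- rnorm(k, mu + bias * sqrt(v), sqrt(tau2 + v))
  data.frame(record_id = sprintf("R%04d", seq_len(k)),
             study_id = sprintf("S%04d", seq_len(k)),
             treatment_id = sprintf("S%04d.T1", seq_len(k)),
             value = y, variance = v, stringsAsFactors = FALSE)
}

#' @export
print.seqherb_simtruth <- function(x, ...) {
  cat("<seqherb_simtruth> seed", x$seed, "\n")
  cat("true intercept", x$config$true_intercept,
      "; sigma2_study", x$config$sigma2_study,
      "; sigma2_treatment", x$config$sigma2_treatment, "\n")
  cat(length(x$u_study), "studies,", length(x$u_treatment), "treatments,",
      length(x$theta), "records\n")
  invisible(x)
}
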