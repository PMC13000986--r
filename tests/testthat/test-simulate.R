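test_that("simulation is reproducible and namespaced by study", {
  cfg <- simulation_config(n_studies = 15)
  a <- simulate_dataset(cfg, seed = 42)
  b <- simulate_dataset(cfg, seed = 42)
  expect_identical(as.data.frame(a$dataset), as.data.frame(b$dataset))
  expect_identical(a$truth$theta, b$truth$theta)
  expect_false(identical(as.data.frame(a$dataset),
                         as.data.frame(simulate_dataset(cfg, seed = 43)$dataset)))

  # adding studies leaves existing studies' records untouched
  big <- simulate_dataset(simulation_config(n_studies = 25), seed = 42)
  small_ids <- a$dataset$record_id
  shared <- as.data.frame(big$dataset)[big$dataset$record_id %in% small_ids, ]
  rownames(shared) <- NULL
  expect_equal(shared, as.data.frame(a$dataset), ignore_attr = TRUE)
})

test_that("generated datasets pass validation and carry the designed shape", {
  sim <- simulate_dataset(simulation_config(), seed = 2)
  ds <- sim$dataset
  expect_s3_class(ds, "seqherb_dataset")
  expect_equal(validation_report(ds)$n_rejected, 0L)
  expect_equal(length(unique(ds$study_id)), 161L)
  expect_gt(nrow(ds), 1200)
  expect_setequal(unique(ds$response_category),
                  c("herbivore_performance", "herbivore_preference",
                    "plant_performance"))
  # category mix near the configured 834:339:172 proportions
  mean_based <- ds[is.na(ds$events_treatment), ]
  frac <- table(mean_based$response_category) / nrow(mean_based)
  expect_equal(unname(frac["herbivore_performance"]), 834 / 1345,
               tolerance = 0.08)
  binary <- ds[!is.na(ds$events_treatment), ]
  expect_equal(nrow(binary) / nrow(ds), 160 / 1505, tolerance = 0.05)
  expect_true(all(binary$outcome %in%
                    c("survival", "feeding_choice", "oviposition_choice")))
  expect_true(all(ds$publication_year >= 1985 & ds$publication_year <= 2023))
  expect_true(all(ds$same_species ==
                    (ds$inducer_species == ds$subsequent_species)))
})

test_that("with zero heterogeneity and huge groups, g concentrates on theta", {
  cfg <- simulation_config(n_studies = 40, sigma2_study = 0,
                           sigma2_treatment = 0,
                           group_sizes = c(4000L, 4000L),
                           binary_fraction = 0)
  sim <- simulate_dataset(cfg, seed = 5)
  es <- suppressWarnings(compute_effect_sizes(sim$dataset))
  theta <- sim$truth$theta[es$record_id]
  expect_lt(max(abs(es$value - theta)), 0.15)
  expect_lt(sd(es$value - theta), 0.04)
})

test_that("realized random effects match the configured components", {
  cfg <- simulation_config(n_studies = 500)
  sim <- simulate_dataset(cfg, seed = 11)
  expect_equal(var(sim$truth$u_study), cfg$sigma2_study, tolerance = 0.1)
  expect_equal(var(sim$truth$u_treatment), cfg$sigma2_treatment,
               tolerance = 0.06)
  # per-record theta decomposition is exact
  ds <- as.data.frame(sim$dataset)
  mean_based <- ds[is.na(ds$events_treatment), ]
  shift <- ifelse(
    mean_based$response_category == "herbivore_performance", 0,
    cfg$moderator_effects[mean_based$response_category])
  rebuilt <- cfg$true_intercept + shift +
    sim$truth$u_study[mean_based$study_id] +
    sim$truth$u_treatment[mean_based$treatment_id]
  expect_equal(unname(sim$truth$theta[mean_based$record_id]),
               unname(rebuilt), tolerance = 1e-12)
})

test_that("infeasible binary configurations are rejected before sampling", {
  expect_error(simulation_config(control_props = c(survival = 1,
                                                   choice = 0.5)))
  expect_error(simulation_config(sigma2_study = -1))
  expect_error(simulation_config(treatments_per_study = c(3L, 2L)))
})

test_that("simulated trees are ultrametric, reproducible, and usable", {
  taxa <- c("Aa bb", "Cc dd", "Ee ff", "Gg hh", "Ii jj")
  t1 <- simulate_tree(taxa, seed = 10)
  t2 <- simulate_tree(taxa, seed = 10)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(ape::is.ultrametric(t1, tol = 1e-8))
  expect_setequal(t1$tip.label, taxa)
  R <- correlation_from_tree(t1)
  expect_silent(validate_phylo_correlation(R))
  two <- simulate_tree(c("x", "y"), seed = 1)
  R2 <- correlation_from_tree(two)
  expect_gte(R2["x", "y"], 0); expect_lt(R2["x", "y"], 1)
  expect_error(simulate_tree("only one"), "at least 2")
})

test_that("taxon effects on a star tree behave like independent effects", {
  # star tree: correlation is the identity, so the taxon term must reproduce
  # the configured variance like any independent random effect
  taxa <- names(seqherb:::.plant_pool())
  star <- ape::stree(length(taxa), type = "star")
  star$tip.label <- taxa
  star$edge.length <- rep(1, nrow(star$edge))
  cfg <- simulation_config(n_studies = 30, sigma2_taxon = 0.4, tree = star)
  set.seed(123)
  devs <- replicate(60, {
    s <- simulate_dataset(cfg, seed = sample.int(1e6, 1))
    s$truth$u_taxon
  })
  expect_equal(mean(apply(devs, 2, var)), 0.4, tolerance = 0.1)
  expect_lt(abs(mean(colMeans(devs))), 0.15)
})
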