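test_that("species representation shares are ranked and sum to 100", {
  tab <- make_records(8L)
  tab$plant_species <- rep(c("Aa bb", "Cc dd", "Ee ff", "Gg hh"), each = 2)
  ds <- dataset_from_table(tab)
  r <- rank_species_by_representation(ds, "plant")
  expect_equal(r$share, rep(25, 4))                 # uniform 4 species
  expect_equal(sum(r$share), 100, tolerance = 1e-9)

  tab$plant_species <- c(rep("Aa bb", 5), rep("Cc dd", 2), "Ee ff")
  r2 <- rank_species_by_representation(dataset_from_table(tab), "plant")
  expect_equal(r2$species[1], "Aa bb")
  expect_equal(r2$share[1], 62.5)
  expect_true(all(diff(r2$share) <= 0))
  expect_equal(sum(r2$share), 100, tolerance = 1e-9)
})

test_that("leave-one-species-out removes the right share and refits", {
  sim <- simulate_dataset(simulation_config(n_studies = 20), seed = 6)
  es <- suppressWarnings(compute_effect_sizes(sim$dataset))
  g <- es[es$metric == "hedges_g", ]
  top <- rank_species_by_representation(g, "plant")$species[1]
  ex <- leave_species_out(g, top, "plant")
  expect_s3_class(ex, "seqherb_exclusion")
  expect_equal(ex$share_of_observations,
               100 * sum(g$plant_species == top) / nrow(g))
  expect_equal(ex$fit$k + sum(g$plant_species == top), nrow(g))
  expect_equal(ex$delta_vs_full,
               unname(ex$fit$beta[1]) - unname(ex$full_fit$beta[1]))

  # excluding an absent species is the identity
  none <- leave_species_out(g, "Notus presentus", "plant")
  expect_equal(none$share_of_observations, 0)
  expect_equal(unname(none$fit$beta), unname(none$full_fit$beta))
})

test_that("an exclusion emptying a moderator level errors by name", {
  tab <- make_records(6L)
  tab$response_category <- "herbivore_performance"
  tab$outcome <- "growth"
  tab$plant_species <- c(rep("Aa bb", 4), "Cc dd", "Cc dd")
  tab$inducer_guild <- c(rep("chewer", 4), "mite", "mite")
  ds <- dataset_from_table(tab)
  es <- compute_effect_sizes(ds)
  expect_error(leave_species_out(es, "Cc dd", "plant",
                                 moderator = ~inducer_guild),
               "mite")
})

test_that("a species driving the effect moves the estimate when excluded", {
  # construct: most species near zero effect, one outlier species strongly
  # negative; exclusion should move the pooled estimate toward zero
  set.seed(77)
  n <- 60
  sp <- rep(c("Outlier sp", "Other one", "Other two", "Other three"),
            length.out = n)
  theta <- ifelse(sp == "Outlier sp", -1.5, 0)
  d <- data.frame(
    record_id = sprintf("r%02d", 1:n),
    study_id = sprintf("s%02d", rep(1:20, each = 3)),
    treatment_id = sprintf("s%02d.t1", rep(1:20, each = 3)),
    plant_species = sp, value = rnorm(n, theta, 0.2),
    variance = runif(n, 0.04, 0.1))
  ex <- leave_species_out(d, "Outlier sp", "plant")
  expect_lt(abs(unname(ex$fit$beta[1])), abs(unname(ex$full_fit$beta[1])))
  expect_lt(unname(ex$full_fit$beta[1]), -0.2)
  expect_lt(abs(unname(ex$fit$beta[1])), 0.2)
})

test_that("LOR validation analyzes the binary subset per outcome class", {
  sim <- simulate_dataset(
    simulation_config(n_studies = 40, binary_fraction = 0.5), seed = 9)
  lv <- lor_validation(sim$dataset)
  expect_s3_class(lv, "seqherb_lor_validation")
  expect_setequal(names(lv$fits), c("survival", "choice"))
  expect_equal(lv$k, sum(!is.na(sim$dataset$events_treatment) &
                           !is.na(sim$dataset$events_control)) -
                 length(attr(lv$es, "exclusions")))
  # true survival LOR is -0.80; the pooled estimate should have that sign
  expect_lt(unname(lv$fits$survival$beta[1]), 0)
  expect_true(all(lv$es$metric == "log_odds_ratio"))
  expect_false(is.null(lv$class_test))
  expect_equal(lv$class_test$qm_df, 1L)

  # identical proportions everywhere -> pooled LOR 0
  tab <- make_records(6L)
  tab$outcome <- "survival"; tab$response_category <- "herbivore_performance"
  tab$mean_treatment <- NA; tab$mean_control <- NA
  tab$sd_treatment <- NA; tab$sd_control <- NA
  tab$n_treatment <- 10L; tab$n_control <- 10L
  tab$events_treatment <- 6L; tab$events_control <- 6L
  lv0 <- lor_validation(dataset_from_table(tab))
  expect_equal(unname(lv0$fits$survival$beta[1]), 0, tolerance = 1e-8)
  expect_error(lor_validation(dataset_from_table(make_records(3L))),
               "no records with binary")
})
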